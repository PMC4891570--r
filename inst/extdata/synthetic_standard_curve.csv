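gene_id,log10_dilution,cq
GAPDH,0,21.058
GAPDH,0,20.971
GAPDH,-1,24.537
GAPDH,-1,24.381
GAPDH,-2,27.873
GAPDH,-2,27.924
GAPDH,-3,31.199
GAPDH,-3,31.3
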