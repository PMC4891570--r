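sample_id,gene_id,replicate,cq
S001,GAPDH,1,19.673
S001,EF1a,1,22.991
S001,Actin,1,24.955
S001,TUA,1,27.674
S002,GAPDH,1,18.398
S002,EF1a,1,21.285
S002,Actin,1,23.202
S002,TUA,1,27.607
S003,GAPDH,1,20.317
S003,EF1a,1,23.414
S003,Actin,1,25.67
S003,TUA,1,28.263
S004,GAPDH,1,17.994
S004,EF1a,1,20.948
S004,Actin,1,22.891
S004,TUA,1,25.835
S005,GAPDH,1,18.806
S005,EF1a,1,21.804
S005,Actin,1,23.681
S005,TUA,1,25.567
S006,GAPDH,1,19.54
S006,EF1a,1,22.28
S006,Actin,1,23.612
S006,TUA,1,27.186
S001,GAPDH,2,19.787
S001,EF1a,2,22.807
S001,Actin,2,24.928
S001,TUA,2,27.492
S002,GAPDH,2,18.431
S002,EF1a,2,21.552
S002,Actin,2,23.318
S002,TUA,2,27.449
S003,GAPDH,2,20.26
S003,EF1a,2,23.258
S003,Actin,2,25.912
S003,TUA,2,28.249
S004,GAPDH,2,18.067
S004,EF1a,2,20.864
S004,Actin,2,23.126
S004,TUA,2,25.675
S005,GAPDH,2,18.779
S005,EF1a,2,21.619
S005,Actin,2,23.677
S005,TUA,2,25.53
S006,GAPDH,2,19.543
S006,EF1a,2,22.33
S006,Actin,2,23.571
S006,TUA,2,26.97
S001,GAPDH,3,19.536
S001,EF1a,3,22.796
S001,Actin,3,24.74
S001,TUA,3,27.772
S002,GAPDH,3,18.541
S002,EF1a,3,21.52
S002,Actin,3,23.334
S002,TUA,3,27.381
S003,GAPDH,3,20.302
S003,EF1a,3,23.376
S003,Actin,3,25.913
S003,TUA,3,28.621
S004,GAPDH,3,18.192
S004,EF1a,3,20.756
S004,Actin,3,23.084
S004,TUA,3,25.807
S005,GAPDH,3,18.692
S005,EF1a,3,21.73
S005,Actin,3,23.712
S005,TUA,3,25.744
S006,GAPDH,3,19.337
S006,EF1a,3,22.302
S006,Actin,3,23.655
S006,TUA,3,26.999
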