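experiment,classifier,negative,neutral,positive_partial,positive_complete
original,kNN,0,0.167,0.741,0.893
original,LVQNN,0,1.0,1.0,0.929
original,MLPI,1.0,0.667,0.778,0.893
original,MLPII,0.5,0.5,0.889,0.893
original,RBFNN,0,0.167,0.444,0.964
original,PNN,0,0.333,0.704,0.750
smote,kNN,0.125,0.417,0.630,0.893
smote,LVQNN,1.0,1.0,1.0,1.0
smote,MLPI,0.5,0.5,0.778,0.930
smote,MLPII,1.0,0.917,0.852,0.930
smote,RBFNN,0.25,0.667,0.444,0.393
smote,PNN,0.375,0.889,0.630,0.679
pca,kNN,0,0.167,0.741,0.893
pca,LVQNN,0,1.0,1.0,0.929
pca,MLPI,0.5,0.5,0.778,0.929
pca,MLPII,0.5,0.5,0.889,0.893
pca,RBFNN,0,0.333,0.667,0.464
pca,PNN,0,0.167,0.778,0.821
smote+pca,kNN,0.5,0.67,0.630,0.893
smote+pca,LVQNN,1.0,1.0,0.963,1.0
smote+pca,MLPI,0.125,0.833,0.704,0.964
smote+pca,MLPII,0.5,0.833,0.815,0.964
smote+pca,RBFNN,0.375,0.417,0.741,0.714
smote+pca,PNN,0.625,0.583,0.556,0.679
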