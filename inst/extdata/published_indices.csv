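dataset,method,dsc,sensitivity,specificity
brats18,SVM,0.8268,0.8306,0.9845
brats18,CNN,0.8556,0.8876,0.9962
brats18,DCNN-F-SVM,0.8958,0.9110,0.9982
clinical,SVM,0.8705,0.9001,0.9586
clinical,CNN,0.8869,0.9152,0.9657
clinical,DCNN-F-SVM,0.9010,0.9236,0.9889
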