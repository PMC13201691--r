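# Published parameter and MAC budgets of the baseline architectures used for
# the reduction-percentage comparisons. These are printed reference
# constants, not recomputed by this package.
model,params_millions,macs_1e9
ResNet,11.69,1.81
DenseNet,7.98,2.83
SqueezeNet,1.25,0.83
MobileNet,3.50,0.30
ShuffleNet,7.39,0.58
MobileViT,0.95,0.20
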