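channel,Se,Sp,ACC,AUC
Channel 1,0.8174,0.9768,0.9626,0.8971
Channel 2,0.8008,0.9741,0.9587,0.8875
Channel 3,0.8113,0.9748,0.9633,0.8931
Fusion,0.8745,0.9624,0.9546,0.9185
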