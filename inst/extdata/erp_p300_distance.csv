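electrode,component,label_pos,label_neg,label_neutral,amplitude_pos,amplitude_neg,amplitude_neutral,printed_theta_deg
Fz,P300,far,near,medium,20.93,14.94,16.29,129.05
FCz,P300,far,near,medium,22.91,16.95,18.29,128.32
Cz,P300,far,near,medium,23.88,18.83,20.23,124.75
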