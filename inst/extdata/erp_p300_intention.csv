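electrode,component,label_pos,label_neg,label_neutral,amplitude_pos,amplitude_neg,amplitude_neutral,printed_theta_deg
central_zero,P300,hostile,kind,non-interactive,12.11,8.86,10.31,123.37
right_part,P300,hostile,kind,non-interactive,12.38,9.95,10.36,126.16
central_zone,P300,hostile,kind,non-interactive,10.91,8.35,9.41,123.36
parietal_zone,P300,hostile,kind,non-interactive,15.49,11.72,12.54,127.59
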