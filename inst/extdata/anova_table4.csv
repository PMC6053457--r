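source,ss,df
regression,4.445999,4
residual,0.502399,22
total,4.948399,26
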