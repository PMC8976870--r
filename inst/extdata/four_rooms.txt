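SS11#2222
SS11#2222
111152222
1111#2222
##G###5##
3333#4444
333354444
3333#4444
3333#4444
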