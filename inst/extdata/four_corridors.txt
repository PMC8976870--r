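####S####
####1####
####1####
####1####
S444G222S
####3####
####3####
####3####
####S####
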