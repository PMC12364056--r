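>N1-U.S-P CDC 2019-nCoV N1 probe
ACCCCGCATTACGTTTGGTGGACC
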