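species,label
M. urceolatum,wide_endemic
M. rostratum,narrow_endemic_lowland
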