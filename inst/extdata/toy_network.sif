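YAL001C	pp	YBL002W	YCL003W
YBL002W	pp	YCL003W
YDL004W	gi	YAL001C
YEL005C	pp	YDL004W
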