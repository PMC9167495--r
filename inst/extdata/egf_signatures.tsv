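# EGF-like domain subtype signatures (name TAB pattern, compact dialect)
PS00022	CxCx(5)Gx(2)C
PS01186	CxCx(2)[GP][FYW]x(4,8)C
PS01187	NxNNC-x(3,14)-C-x(3,7)-CxxBxxxxAxC-x(1,6)-C-x(8,13)-Cx
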