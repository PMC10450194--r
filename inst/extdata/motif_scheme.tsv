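protein	pattern	metal	variant
uS4	CxxC-CxxxxC	iron_sulfur	canonical
uS14	CxxC-CxxC	zinc	canonical
bS18	CxxC-CxxH	zinc	canonical
uL24	CxxC-CxxC	zinc	canonical
bL28	CxxC-CxxC	zinc	canonical
bL31	CxxC-CxxC	zinc	canonical
bL32	CxxC-CxxC	zinc	canonical
bL33	CxxC-CxxC	zinc	CCCC
bL33	CxxC-CxxD	zinc	CCCD
bL33	CxxC-CxxE	zinc	CCCE
bL36	CxxC-CxxH	zinc	canonical
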