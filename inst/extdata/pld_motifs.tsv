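motif	pattern
3	IYIENQ[FY]F
4	[GK]GPR[EQ]PWHD[LIV]H[CS][KR][IL][ED]GPA[YW]DVLTNFE[QE]RWRK[AQ]G[G][PW][KD]GLVK
HKD	H.K....D
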