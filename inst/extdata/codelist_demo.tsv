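raw_code	category
K04..	AKI
AKI01	AKI
K050.	ESKD
ESKD1	ESKD
7B00.	transplant
TXK01	transplant
7L1A.	dialysis
DIAL1	dialysis
7B06.	nephrectomy
NEPH1	nephrectomy
62...	pregnancy
PREG1	pregnancy
C10..	diabetes
DM01	diabetes
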