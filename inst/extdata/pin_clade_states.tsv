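clade	label	lineage
PINZ	canonical	BC
PINWXY	noncanonical	BNC
PINA	canonical	BC
PIND	noncanonical	BNC
Lyco1	canonical	Lyco1
Lyco2	canonical	Lyco2
PIN5	noncanonical	Eu1
PINI	canonical	Eu1
PIN12	semicanonical	Eu1
PINK	canonical	Eu2
PINL	canonical	Eu2
PINM	canonical	Eu2
PINN	canonical	Eu2
PIN6	semicanonical	Eu2
PINJ	canonical	Eu3
PINE	canonical	Eu3
PINF	canonical	Eu3
PING	canonical	Eu3
PINH	canonical	Eu3
PIN1	canonical	Eu3
PIN9	noncanonical	Eu3
PIN11	canonical	Eu3
PIN2	canonical	Eu3
PIN3	canonical	Eu3
PIN8	noncanonical	Eu3
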