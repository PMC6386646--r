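truth	lying	running	sitting	stairs	standing	walking
lying	38874	166	6920	830	3938	0
running	1587	31593	0	12402	791	11693
sitting	12483	0	38596	864	8030	154
stairs	559	6505	1929	46751	2320	6156
standing	887	0	5127	0	54300	77
walking	2146	12	555	4846	5976	52455
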