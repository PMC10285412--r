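# Printed atomic distances in the 2.2-A mito-ribosome model, as spot
# checks for a locally provided coordinate file. Alternative atoms are
# separated by '|' (the minimum is compared).
from	to	expected	tol
12S:460:O2'	12S:290:OP1	3.217	0.005
12S:283:O6	MRPS12:47:NE|NH1|NH2	2.39	0.01
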