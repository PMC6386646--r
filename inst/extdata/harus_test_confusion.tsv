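truth	walking	walking_upstairs	walking_downstairs	sitting	standing	laying
walking	11238	0	935	0	0	0
walking_upstairs	0	11070	1297	0	12	0
walking_downstairs	0	0	11659	0	40	0
sitting	0	0	0	11037	2798	0
standing	0	24	96	1926	12546	0
laying	0	19	0	0	0	15266
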