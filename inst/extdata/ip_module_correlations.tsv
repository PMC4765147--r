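metabolite	module	r	p
IP1	dodgerblue4	0.87	3e-4
IP2	salmon1	-0.98	4e-4
IP2	burlywood2	0.96	3e-4
IP3	burlywood2	0.86	3e-4
IP4	magenta2	-0.87	2e-3
IP5	cornsilk	0.91	1e-4
IP6	steelblue4	0.81	2e-4
IP6	cornsilk	0.86	3e-4
IP6	magenta2	-0.87	3e-4
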