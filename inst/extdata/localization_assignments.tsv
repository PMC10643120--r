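protein	category
gp62	nucleus
gp78	nucleus
gp108	nucleus
gp131	nucleus
gp134	nucleus
gp200	nucleus
gp210	nucleus
gp257	nucleus
gp2	shell
gp61	shell
gp63	shell
gp64	shell
gp148	shell
gp375	shell
gp12	bouquet
gp164	bouquet
gp166	bouquet
gp233	bouquet
gp355	bouquet
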