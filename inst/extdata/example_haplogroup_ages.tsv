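# EXAMPLE age-contrast table (illustrative values only, user-supplied in
# real analyses): delta_age = estimated haplogroup founder age in Europe
# minus age in the Near East, years.
haplogroup	delta_age
U	12000
V	1500
H	-2000
J	-8000
T	-6500
K	-5000
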