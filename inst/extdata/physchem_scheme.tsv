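# Physicochemical recoding scheme: residue one-letter code -> category id.
# Cys, His and Pro are deliberately singleton categories (no published
# grouping asserts their similarity to any other residue).
residue	category	display
A	tiny	Tiny
G	tiny	Tiny
S	small_hydroxyl	Small Hydroxyl
T	small_hydroxyl	Small Hydroxyl
E	acidic	Acidic
D	acidic	Acidic
Q	amine	Amine
N	amine	Amine
K	basic	Basic
R	basic	Basic
I	aliphatic	Aliphatic
L	aliphatic	Aliphatic
M	aliphatic	Aliphatic
V	aliphatic	Aliphatic
W	aromatic	Aromatic
Y	aromatic	Aromatic
F	aromatic	Aromatic
C	C	C
H	H	H
P	P	P
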