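pinyin	slots
an	-|-|a|n
ceng	tsʰ|-|ə|ŋ
du	t|-|u|-
guo	k|u|o|-
jia	tɕ|i|a|-
jian	tɕ|i|ɛ|n
jie	tɕ|i|ɛ|-
jing	tɕ|-|i|ŋ
jue	tɕ|y|ɛ|-
ma	m|-|a|-
shuai	ʂ|u|a|ɪ
shuan	ʂ|u|a|n
tu	tʰ|-|u|-
wai	-|u|a|ɪ
wu	-|-|u|-
xiang	ɕ|i|a|ŋ
xie	ɕ|i|ɛ|-
xiong	ɕ|i|o|ŋ
ye	-|i|ɛ|-
yi	-|-|i|-
zai	ts|-|a|ɪ
zan	ts|-|a|n
zeng	ts|-|ə|ŋ
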