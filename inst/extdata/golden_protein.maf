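##maf version=1
# pinned golden fixture: protein alphabet with an out-of-alphabet '*'

a score=5
s human.p1 0 4 + 100 MKWY
s mouse.p1 0 4 + 100 MK*Y
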