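##maf version=1
# pinned golden fixture: minus strand, missing score, 'F' quality, gap, N

a score=100.0
s hg38.chr1 10 5 + 1000 ACGT-A
s mm10.chr2 20 5 - 900 AC-GTA
q mm10.chr2        99-F10

a
s hg38.chr1 15 4 + 1000 GGGG
s rn6.chr3 0 4 + 500 GGNG
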