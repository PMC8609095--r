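file	md5
table_tshr.tsv	78c4f66fd32c27969a3921e62fd65873
table_tg.tsv	f3d903983d89bb7ef1c49b04a0da5bee
table_tpo.tsv	d5648a092f71a3fe3a1a7ff6d0e98947
reference_segments.tsv	7c5df42c3a6365e9491376dbee46c1ae
epitopes.tsv	a8d9d5b9ac2a3fc05a5a31063d6763d4
domains.tsv	5b058481e3c11a4e4ca834ce69975ec7
areas_of_interest.txt	33e91727c5f49828182de232f088b952
BLOSUM62.txt	ad8a2640fc7ae510b71d4c6b944d898c
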