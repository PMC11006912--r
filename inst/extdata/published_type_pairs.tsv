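snpeff_term	vep_term	n
Frameshift	Frameshift	15999
Splice acceptor	Splice acceptor	1800
Splice donor	Splice donor	2066
Start lost	Start lost	277
Stop gained	Stop gained	2685
Stop lost	Stop lost	171
Transcript ablation	Transcript ablation	2
Exon loss	Frameshift	3
Exon loss	Inframe deletion	1
Exon loss	Splice acceptor	11
Exon loss	Splice donor	25
Frameshift	Inframe deletion	13
Frameshift	Inframe insertion	3
Frameshift	Protein altering	2
Frameshift	Splice acceptor	537
Frameshift	Splice donor	765
Frameshift	Start lost	10
Frameshift	Stop gained	256
Frameshift	Stop lost	5
Gene fusion	Frameshift	2
Gene fusion	Inframe deletion	1
Gene fusion	Splice acceptor	2
Gene fusion	Splice donor	1
Inframe deletion	Splice acceptor	10
Inframe deletion	Splice donor	5
Inframe deletion	Start lost	4
Inframe deletion	Stop lost	1
Inframe insertion	Frameshift	1
Missense	Splice acceptor	2
Missense	Splice donor	1
Missense	Start lost	34
Splice acceptor	Frameshift	103
Splice acceptor	Inframe deletion	3
Splice acceptor	Inframe insertion	64
Splice acceptor	Missense	14
Splice acceptor	Protein altering	6
Splice acceptor	Splice donor	404
Splice acceptor	Stop gained	40
Splice donor	Frameshift	374
Splice donor	Inframe insertion	157
Splice donor	Missense	26
Splice donor	Protein altering	6
Splice donor	Stop gained	7
Start lost	Missense	15
Stop gained	Missense	20
Stop gained	Splice acceptor	1
Stop gained	Splice donor	1
Stop lost	Missense	5
Stop lost	Splice acceptor	3
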