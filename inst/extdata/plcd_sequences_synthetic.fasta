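>A1_LCD synthetic stand-in (135 aa, PLCD-like, net positive)
SGGFGGNSMSGFSGSGNKGFGNGGGNGFGRSDKTGYGSSNVMTYSGGNGRGFNGGAGSDFPGEGSGGYGGSSSGYRASGSGGFSQNGGSNYSNSSNGGYGGQGGRSYGQQNGASYKSQGGRSYRPGRGSSFQGSD
>A1_LCD_12D synthetic stand-in (A1_LCD with 12 Gly/Ser->Asp substitutions)
DGGFGGNSMSDFSGSGNKGFGNDGGNGFGRSDKTDYGSSNVMTYSGGNDRGFNGGAGSDFPGEDSGGYGGSDSGYRASGSGDFSQNGGSNYSNSDNGGYGGQGDRSYGQQNGASYKSQGDRSYRPGRGSSFQGDD
>FUS_LCD synthetic stand-in (214 aa, PLCD-like, weakly net negative)
SGQYTTPGGGGTYQEGPSPAFMPSSTTQGYQPGSGGGPYQGSGTQAYNSQGSQTGYQTGNQSGYGSSQPSDGYGPQGPSSYSTGSSSSSYGQSDQASYSSGSSSGQYQTSPSQPGYGQGSSSSYQANGGGSTYQNQTTSGYSQPGSSSGYMGSQGPQYGSNDSNGGYTQASPSQYNTQQSQQPFGPNGDQQRYSPKGGTGYGSAGSSTPYSGTG
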