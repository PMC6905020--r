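>synth001
HSHYHMYKHSGKEAYKKGRRVSRSHGHCGYQKLRKKGKKAQIIKTCHRHHTRATPV
>synth002
FKWICYAMMPYFTGKGSHSRKHGTHVLMFTIKKRTGVEWPEY
>synth003
RSHTKTSGQGTKHSCTRKKRKPQHRYCTVDPNEHKVFNTHL
>synth004
TGGSHHKYMNVFNLKRGTRKRLDRWWDCLAMARGGGRTLMTKKRGTSTHHRHGLRFVYT
>synth005
HRSGKHKSFAYCSLCKHSKKTHHFACSNKMAMAGRRHGIC
>synth006
WRTEHHKHWSWSSAFTAHDGIAGRSRHSQVHTSRGGGVHTRHTHKHSKRRGVDHEGCD
>synth007
KSTHGGKHSHGVDIMFHQHEWRWAKSGGKTDYILANIQEWNVWTHSHGHTS
>synth008
FCEHSKRTTGKGTGTRYKESMHVEPHYKHHKKSFFNICVIMKRYHRHRTGRSHRSHSKSW
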