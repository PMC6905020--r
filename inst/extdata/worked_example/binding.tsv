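synth001	ION	1 10 18 25 36 37 49
synth002	ION	17 20 22 23 34
synth003	ION	1 3 5 12 18
synth004	ION	1 5 17 35 43 48 51
synth005	ION	1 6 19 21 36
synth006	ION	25 33 35 41 45 48 49
synth007	ION	2 6 9 27 46 50
synth008	ION	6 11 14 30 47 52 57
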