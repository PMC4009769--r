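chrom	start	end	region
Chr1	1	11100000	arm
Chr1	11100001	14100000	pericentromere
Chr1	14100001	16100000	centromere
Chr1	16100001	19100000	pericentromere
Chr1	19100001	30427671	arm
Chr2	1	1	arm
Chr2	2	2600000	pericentromere
Chr2	2600001	4600000	centromere
Chr2	4600001	7600000	pericentromere
Chr2	7600001	19698289	arm
Chr3	1	9800000	arm
Chr3	9800001	12800000	pericentromere
Chr3	12800001	14800000	centromere
Chr3	14800001	17800000	pericentromere
Chr3	17800001	23459830	arm
Chr4	1	1	arm
Chr4	2	3000000	pericentromere
Chr4	3000001	5000000	centromere
Chr4	5000001	8000000	pericentromere
Chr4	8000001	18585056	arm
Chr5	1	7900000	arm
Chr5	7900001	10900000	pericentromere
Chr5	10900001	12900000	centromere
Chr5	12900001	15900000	pericentromere
Chr5	15900001	26975502	arm
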