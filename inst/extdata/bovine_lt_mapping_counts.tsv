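sample_id	n_reads	n_mapped	n_uniquely_mapped	n_uniquely_mapped_pairs
LIM1	86352760	65739933	61587716	32792300
LIM2	72251962	54576643	51574445	26484662
LIM3	90678870	68916620	65139874	32399058
LIM4	74649210	61346058	56117512	25646394
LIM5	72416218	50206044	47169853	24089814
LIM6	80220062	61543271	58093383	30477552
LIM7	38198732	30174318	28421388	15891664
LIM8	27278276	21840568	20558269	12590540
LIM9	59836970	46205282	43701020	23843178
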