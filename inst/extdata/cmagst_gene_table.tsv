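gene_id	chromosome	start	end	strand
CmaGSTU1	Chr13	8381645	8382352	+
CmaGSTU2	Chr11	1483599	1484338	+
CmaGSTU3	Chr14	13801828	13805918	+
CmaGSTU4	Chr06	7777316	7778827	-
CmaGSTU5	Chr00	47643604	47645087	-
CmaGSTU6	Chr06	8499592	8500393	-
CmaGSTU7	Chr14	13214607	13217686	-
CmaGSTU8	Chr06	8501349	8502406	+
CmaGSTU9	Chr14	13213235	13214322	-
CmaGSTU10	Chr03	4366133	4366923	+
CmaGSTU11	Chr07	5378533	5380070	-
CmaGSTU12	Chr16	2333498	2334374	+
CmaGSTU13	Chr04	3269916	3271375	-
CmaGSTU14	Chr16	2326120	2328293	+
CmaGSTU15	Chr04	3271577	3272321	-
CmaGSTU16	Chr04	3273122	3286431	-
CmaGSTU17	Chr04	15857294	15858045	-
CmaGSTU18	Chr04	3268691	3269778	-
CmaGSTF1	Chr08	2344840	2346569	+
CmaGSTF2	Chr08	2346863	2348162	-
CmaGSTF3	Chr12	1988809	1990016	-
CmaEF1G1	Chr16	4206363	4213994	+
CmaEF1G2	Chr04	4645271	4652681	+
CmaEF1G3	Chr06	5603706	5606718	-
CmaGSTT1	Chr16	3054792	3058033	-
CmaGSTT2	Chr00	47643604	47645087	+
CmaGSTZ1	Chr02	3895323	3899120	+
CmaGSTZ2	Chr02	3887013	3892301	+
CmaGSTZ3	Chr06	7652425	7656514	+
CmaGSTL1	Chr06	1588222	1591488	-
CmaGHR1	Chr18	3671672	3674403	-
CmaGHR2	Chr19	681203	684746	+
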