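snp	chrom	pos	derivation
Gga_rs14303341	27	1111875	table4_center
Gga_rs14340790	3	35026541	table4_center
Gga_rs16254447	3	35548152	table4_endpoint
Gga_rs14341204	3	35585000	interpolated
Gga_rs14341224	3	35620000	interpolated
Gga_rs14341242	3	35655000	interpolated
Gga_rs14341255	3	35690000	interpolated
GGaluGA216762	3	35719953	table4_endpoint
Gga_rs16228738	3	5608301	table4_center
GGaluGA069801	10	11503758	table4_center
Gga_rs15717370	14	822937	table4_endpoint
Gga_rs14068999	14	833997	table4_endpoint
Gga_rs14075705	14	7320547	table4_center
Gga_rs13622160	23	2894945	table4_center
GGaluGA188871	23	3381182	table4_endpoint
Gga_rs14290610	23	3632163	table4_endpoint
GGaluGA333545	8	28615409	table4_endpoint
Gga_rs14658668	8	28670000	interpolated
Gga_rs16650878	8	28725822	table4_endpoint
Gga_rs14748835	Z	59761642	table4_endpoint
Gga_rs16094710	Z	59830000	interpolated
Gga_rs16758057	Z	59890315	table4_endpoint
Gga_rs13749637	1	32028151	table4_endpoint
Gga_rs15227054	1	32046400	table4_endpoint
Gga_rs16002106	13	14786787	table4_endpoint
GGaluGA097211	13	14830000	interpolated
GGaluGA097233	13	14871343	table4_endpoint
Gga_rs14988623	13	6367549	table4_center
Gga_rs14416916	18	10095245	table4_endpoint
Gga_rs15469971	18	10488532	table4_endpoint
Gga_rs10729280	18	10976127	table4_endpoint
Gga_rs13569377	18	11080354	table4_endpoint
Gga_rs14319575	3	5625936	table4_center
GGaluGA236122	3	98246994	table4_endpoint
Gga_rs14402423	3	98387484	table4_endpoint
Gga_rs16674724	9	17175422	table4_center
Gga_rs13561344	6	1890195	table4_endpoint
Gga_rs14560750	6	2031763	table4_endpoint
Gga_rs15583507	10	12939689	table4_endpoint
Gga_rs14009265	10	13176210	table4_endpoint
Gga_rs14368109	3	62813708	table4_endpoint
Gga_rs14368127	3	62823180	table4_endpoint
GGaluGA071224	10	14162468	table4_center
Gga_rs14380677	3	76475164	table4_center
Gga_rs16306728	3	78045258	table4_center
GGaluGA231041	3	79988812	table4_center
GGaluGA194739	0	1000000	invented
GGaluGA012915	1	50000000	invented
Gga_rs13866305	1	120000000	invented
Gga_rs13717259	3	20000000	invented
GGaluGA060937	1	150000000	invented
GGaluGA101229	14	5000000	invented
Gga_rs16026770	2	30000000	invented
GGaluGA146662	2	90000000	invented
Gga_rs14214495	2	140000000	invented
Gga_rs15683090	13	10000000	invented
Gga_rs14388313	3	45000000	invented
Gga_rs14521876	5	30000000	invented
Gga_rs16222762	3	55000000	invented
Gga_rs14272866	20	8000000	invented
Gga_rs15480969	4	60000000	invented
Gga_rs14276105	20	12000000	invented
GGaluGA317680	7	20000000	invented
Gga_rs15718248	14	12000000	invented
GGaluGA066690	10	5000000	invented
GGaluGA066877	10	5100000	invented
Gga_rs15991936	Z	30000000	invented
Gga_rs15589655	10	18000000	invented
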