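gene	chrom	start	stop	pli
EFEMP1	chr2	56093102	56151274	0.99
BCL11A	chr2	60678302	60780633	1.00
PAPOLG	chr2	60983912	61045379	0.99
REL	chr2	61108752	61150667	0.99
PUS10	chr2	61244119	61332131	0.02
PEX13	chr2	61245032	61279125	0.01
AHSA2	chr2	61406978	61414341	0.01
USP34	chr2	61414547	61697962	1.00
XPO1	chr2	61704984	61765313	1.00
CCT4	chr2	62095465	62113850	0.99
B3GNT2	chr2	62423877	62452559	0.93
EHBP1	chr2	62844617	63200205	0.35
VPS54	chr2	64067955	64179639	0.98
AFTPH	chr2	64766016	64818574	0.97
ACTR2	chr2	65455617	65498473	0.99
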