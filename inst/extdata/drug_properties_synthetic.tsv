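drug	mw	fu	ct	logp	approval_year
aripiprazole	448.4	0.01	350	4.5	2002
asenapine	285.8	0.05	5	4.9	2009
brexpiprazole	433.6	0.01	40	5.0	2015
cariprazine	427.4	0.08	30	4.9	2015
chlorpromazine	318.9	0.03	300	5.4	1957
clozapine	326.8	0.05	600	3.2	1989
fluphenazine	437.5	0.01	10	4.4	1959
haloperidol	375.9	0.08	10	4.3	1967
iloperidone	426.5	0.03	10	3.1	2009
loxapine	327.8	0.03	30	3.6	1975
lurasidone	492.7	0.01	40	5.6	2010
olanzapine	312.4	0.07	80	3.0	1996
paliperidone	426.5	0.26	60	1.8	2006
perphenazine	404.0	0.08	4	4.2	1957
pimozide	461.5	0.01	20	6.3	1984
quetiapine	383.5	0.17	500	2.8	1997
risperidone	410.5	0.10	60	3.3	1993
thiothixene	443.6	0.10	15	4.6	1967
ziprasidone	412.9	0.01	200	3.8	2001
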