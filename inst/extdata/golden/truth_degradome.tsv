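transcript_id	pos	count	category
ARFL1	19	1	4
ARFL1	74	1	4
ARFL1	90	1	4
ARFL1	114	1	4
ARFL1	228	1	4
ARFL1	259	1	4
ARFL1	260	1	4
ARFL1	312	30	1
ARFL1	413	1	4
ARFL1	451	1	4
ARFL1	563	1	4
PARA1	27	1	4
PARA1	78	1	4
PARA1	212	30	1
PARA1	329	1	4
PARA1	373	1	4
PARA1	433	1	4
PARA1	612	1	4
PARA1	634	1	4
PARA1	639	1	4
PARA1	670	1	4
PARA1	683	1	4
PARA1	700	1	4
PARA1	714	1	4
PARA1	762	1	4
PARA2	31	1	4
PARA2	38	1	4
PARA2	39	1	4
PARA2	201	1	4
PARA2	342	30	1
PARA2	392	1	4
PARA2	407	1	4
PARA2	424	1	4
PARA2	673	1	4
PARA3	86	1	4
PARA3	162	30	1
PARA3	234	1	4
PARA3	308	1	4
PARA3	354	1	4
PARA3	451	1	4
PARA3	567	1	4
PARA3	646	1	4
PARA3	648	1	4
PARA3	657	1	4
PARA3	730	1	4
TASL1	39	1	4
TASL1	90	1	4
TASL1	99	1	4
TASL1	112	30	1
TASL1	313	1	4
TASL1	351	30	1
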