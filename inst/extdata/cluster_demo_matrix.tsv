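gene_id	subj1_t0.0	subj1_t4.0	subj1_t24.0	subj2_t0.0	subj2_t0.5	subj2_t4.0	subj3_t0.0	subj3_t0.5	subj4_t0.0	subj4_t0.5	subj5_t0.0	subj5_t0.5	subj6_t0.0	subj6_t0.5	subj6_t24.0	subj7_t0.0	subj7_t0.5	subj8_t0.0	subj8_t4.0	subj8_t24.0	subj9_t0.0
down_01	7.15442593803983	6.43661573176557	5.0272859272742	7.41005490610647	7.07384548340327	6.42347731722705	7.5380812969355	7.45200706559386	7.09056637348408	7.11759313906488	8.07327570791822	7.62637468496612	6.9956616202795	7.03662635291288	5.18117644220098	7.48698391496775	7.18479762254292	7.65088805631533	6.60889023604888	5.68461063132031	7.13624398400005
down_02	10.6052315122582	9.09516014728544	8.6139688090815	10.4386328256257	10.0013382269091	9.06879904170463	10.0102086374428	9.58749815153269	10.5837341393614	9.86212075077335	10.6077323244323	9.91664496286707	10.3773377533726	10.0828699204607	8.6675118301982	10.6467264594614	10.2412068082399	9.88132417449077	8.88130663579268	7.98983396186787	10.4111843059327
down_03	9.38229814702821	9.00010777494289	7.24810233331859	9.07129562319109	8.97645671083619	8.7128636261463	8.44628499907812	8.6452206254556	8.87357866386033	8.94815127327685	9.07496995781609	8.94973825838327	9.10050920031009	8.81129094068619	6.88982882649923	8.87186527161691	8.90756306277934	9.44611686782727	9.12085994491667	7.1677171438506	9.00859896359658
up_01	7.06693521263836	7.67371237796798	9.34670225249152	7.31375999855355	7.53300913807954	7.79566462230157	8.14842314143187	8.19314095963377	7.57294130957077	7.75755160455029	7.47880888342589	7.51170419729024	7.46094943810539	7.65081923105515	9.53006511382998	7.92869708661957	7.95207805252176	7.79799879383836	8.30579864179087	9.84494196995428	7.4583537690791
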