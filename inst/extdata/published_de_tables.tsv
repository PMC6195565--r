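table	family	mirna	log2FC	log2CPM	pValue	FDR
hPSC	mir-17-92	hsa-miR-17-5p	-4.34568	9.012717	0.000855	0.00184
hPSC	mir-17-92	hsa-miR-18a-5p	-4.12927	5.365265	0.002687	0.005021
hPSC	mir-17-92	hsa-miR-20a-5p	-3.39956	9.942874	5.93E-05	0.000159
hPSC	mir-17-92	hsa-miR-92a-3p	-2.28835	14.64776	0.005145	0.009065
hPSC	mir-200	hsa-miR-200a-3p	-4.18521	6.916635	0.005677	0.009636
hPSC	mir-200	hsa-miR-200a-5p	-4.53501	5.812451	0.000615	0.001422
hPSC	mir-200	hsa-miR-200b-3p	-6.81357	10.64906	1.04E-06	4.1E-06
hPSC	mir-200	hsa-miR-429	-9.26846	6.001451	4.62E-08	2.59E-07
hPSC	mir-302/367	hsa-miR-302a-3p	-15.6675	12.33651	9.32E-25	1.3E-22
hPSC	mir-302/367	hsa-miR-302a-5p	-13.4935	17.28532	5.1E-20	1.89E-18
hPSC	mir-302/367	hsa-miR-302b-3p	-13.5506	16.09634	9.86E-18	3.04E-16
hPSC	mir-302/367	hsa-miR-302c-3p	-15.5738	12.24285	1.41E-24	1.3E-22
hPSC	mir-302/367	hsa-miR-302c-5p	-11.0944	9.555795	6.18E-16	1.27E-14
hPSC	mir-302/367	hsa-miR-302d-3p	-13.7161	12.16085	4.98E-23	3.07E-21
hPSC	mir-302/367	hsa-miR-302d-5p	-8.71179	5.475559	5.61E-07	2.36E-06
hPSC	mir-302/367	hsa-miR-367-3p	-9.95691	6.665547	2.02E-09	1.29E-08
hPSC	mir-371/373	hsa-miR-371a-3p	-8.62254	5.393327	1E-06	4.03E-06
hPSC	mir-371/373	hsa-miR-371a-5p	-11.2134	7.898332	1.21E-12	1.32E-11
hPSC	mir-371/373	hsa-miR-372-3p	-13.3871	11.83298	3.78E-22	1.75E-20
hPSC	mir-371/373	hsa-miR-373-3p	-9.00191	5.748367	1.49E-07	7.63E-07
hPSC	C19MC	hsa-miR-516a-5p	-8.51958	5.296551	2.2E-06	7.52E-06
hPSC	C19MC	hsa-miR-516b-5p	-9.69778	8.987653	1.64E-13	2.09E-12
hPSC	C19MC	hsa-miR-517a-3p	-9.14288	5.88151	9.03E-08	4.78E-07
hPSC	C19MC	hsa-miR-517b-3p	-8.77055	5.528605	1.4E-06	5.17E-06
hPSC	C19MC	hsa-miR-518b	-10.5662	7.260425	5.46E-11	4.39E-10
hPSC	C19MC	hsa-miR-520c-3p	-8.57565	5.348277	1.68E-06	5.87E-06
hPSC	C19MC	hsa-miR-520f-3p	-10.0952	6.799461	1.09E-09	7.46E-09
hPSC	C19MC	hsa-miR-520g-3p	-8.2576	6.709774	1.25E-08	7.47E-08
hPSC	C19MC	hsa-miR-522-3p	-8.44063	5.225189	2.99E-06	1.01E-05
hPSC	C19MC	hsa-miR-523-3p	-8.20928	5.013337	1.17E-05	3.49E-05
hPSC	C19MC	hsa-miR-526b-5p	-8.8302	5.585032	7.1E-07	2.92E-06
hPSC	C19MC	hsa-miR-1323	-11.8527	8.531433	1.69E-13	2.09E-12
ATMSC	let-7/mir-98	hsa-let-7a-3p	9.151431	6.477715	1.41E-05	4.15E-05
ATMSC	let-7/mir-98	hsa-let-7a-5p	4.438344	13.48553	5.38E-06	1.72E-05
ATMSC	let-7/mir-98	hsa-let-7b-3p	9.306488	6.621799	5.87E-05	0.000159
ATMSC	let-7/mir-98	hsa-let-7b-5p	9.666006	14.19212	5.27E-13	6.09E-12
ATMSC	let-7/mir-98	hsa-let-7c-5p	6.377311	10.45171	5.57E-09	3.43E-08
ATMSC	let-7/mir-98	hsa-let-7e-5p	5.912685	9.64524	2.31E-07	1.15E-06
ATMSC	let-7/mir-98	hsa-let-7f-5p	6.292228	12.90261	1.65E-09	1.09E-08
ATMSC	let-7/mir-98	hsa-let-7i-5p	8.040472	14.0149	9.88E-12	9.62E-11
ATMSC	let-7/mir-98	hsa-miR-98-5p	10.92755	8.203416	1.92E-08	1.11E-07
ATMSC	mir-10/100	hsa-miR-10a-5p	7.995657	13.27917	2.67E-10	1.9E-09
ATMSC	mir-10/100	hsa-miR-10b-3p	7.559436	5.017372	0.001355	0.002849
ATMSC	mir-10/100	hsa-miR-10b-5p	8.498145	14.36205	8.18E-12	8.41E-11
ATMSC	mir-10/100	hsa-miR-100-5p	4.009269	13.98291	0.000211	0.000519
ATMSC	mir-125	hsa-miR-125a-5p	3.250007	10.45281	0.000975	0.002073
ATMSC	mir-125	hsa-miR-125b-1-3p	5.844325	8.026384	0.004338	0.007792
ATMSC	mir-125	hsa-miR-125b-5p	6.371527	9.723062	3.62E-07	1.67E-06
ATMSC	mir-196	hsa-miR-196a-5p	7.26496	7.494054	0.001717	0.003378
ATMSC	mir-196	hsa-miR-196b-5p	7.761247	5.191769	0.00082	0.001792
ATMSC	mir-199	hsa-miR-199a-3p	3.994405	8.941022	0.000276	0.000671
ATMSC	mir-199	hsa-miR-199a-5p	5.906115	9.147113	3.88E-06	1.28E-05
ATMSC	mir-199	hsa-miR-199b-3p	3.924898	8.599356	0.000403	0.000968
ATMSC	mir-199	hsa-miR-199b-5p	3.021359	7.643468	0.003009	0.005567
ATMSC	mir-148/152	hsa-miR-152-3p	4.293438	9.473328	4.73E-05	0.000131
ATMSC	mir-148/152	hsa-miR-22-3p	4.552346	10.88709	5.96E-06	1.84E-05
ATMSC	mir-148/152	hsa-miR-24-3p	2.867598	10.70777	0.001581	0.003249
ATMSC	mir-148/152	hsa-miR-27a-3p	2.971421	11.04311	0.001444	0.003001
ATMSC	mir-148/152	hsa-miR-143-3p	6.997134	13.46121	1.9E-11	1.64E-10
ATMSC	mir-148/152	hsa-miR-144-3p	10.80517	8.085471	1.68E-06	5.87E-06
ATMSC	mir-148/152	hsa-miR-193b-5p	4.056847	6.250916	0.002251	0.004294
ATMSC	mir-148/152	hsa-miR-195-3p	3.357619	6.148953	0.004834	0.008599
ATMSC	mir-148/152	hsa-miR-542-3p	4.172502	5.528398	0.005462	0.009455
ATMSC	mir-148/152	hsa-miR-615-3p	9.77289	10.03215	2.62E-05	7.36E-05
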