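gene_id	case_01	case_02	case_03	case_04	case_05	ctrl_01	ctrl_02	ctrl_03	ctrl_04	ctrl_05
gene_01	8.862371619	8.334786426	8.773385965	8.623644321	9.018049467	9.121198392	8.586994592	9.262572309	8.809606714	8.552906491
gene_02	4.548893188	3.849829383	4.586395007	5.582063046	4.508310149	6.259932732	5.945378999	6.286408153	6.337752252	5.578326415
gene_03	10.03931236	9.956138578	9.485789371	9.726765386	10.28675552	 10.2038653	9.823353224	10.34220387	9.754986951	10.03257616
gene_04	5.186062863	4.816594949	4.563947706	5.047219121	5.351569648	5.812346705	5.700520404	5.168160652	5.880397146	4.567864259
gene_05	6.209116693	 5.80648071	6.928315184	6.424419753	6.786135065	6.736064237	6.207018003	6.814863567	6.885514858	7.513555428
gene_06	5.618377524	6.363499142	 5.52380941	6.035521472	6.409167567	8.037564854	 7.89579316	6.957899456	  8.5332449	7.520246631
gene_07	3.867343805	4.606362331	4.748029618	4.147498729	4.110427385	3.008289464	2.773321523	2.487070453	 3.37478102	3.169762631
gene_08	5.123122419	6.137403233	5.161641496	5.752570572	5.479228774	4.802038101	6.653389646	6.063042767	5.842599838	4.810605454
gene_09	6.570127759	8.320567568	8.261887745	8.412916377	8.082966236	5.966912712	6.069146934	7.083270538	6.426199274	6.551148893
gene_10	5.859934346	5.976034045	5.507934924	6.886891012	5.409162017	5.668871703	5.975001272	6.329233776	5.563925407	5.783691546
gene_11	6.861641191	7.519514567	7.297511926	8.074018645	7.393115568	 6.42092623	7.507151605	7.209865295	7.309598882	7.339838288
gene_12	7.569499548	6.758968098	6.444240752	5.790413772	7.635856804	7.359494193	6.345806899	7.031531838	6.190981144	6.266956534
gene_13	6.835881504	6.152979576	6.553600251	6.337036704	5.582494047	5.306976324	6.466908413	6.352436113	5.245225683	 5.81761853
gene_14	9.539056725	9.652434545	 8.64321951	8.876575117	8.209604782	9.819399978	8.170026413	8.705534446	8.414420763	7.829891061
gene_15	4.169303223	5.083250312	5.278634743	4.684085107	4.421441053	3.963742024	 5.29538961	4.103215025	4.755690576	4.112829716
gene_16	5.413555339	6.371959145	6.538133842	6.477022031	5.878401636	6.050492333	6.577446763	5.653657502	5.456634194	6.756591724
gene_17	7.999076945	9.120519184	8.380482974	9.098778101	7.722978446	8.123001056	8.272119394	 7.71616855	8.564252328	8.054137895
gene_18	7.665118423	6.838273995	6.809345637	7.592864797	8.000441693	7.190010463	6.969517958	7.232652188	7.469153424	6.809175439
gene_19	6.915254076	6.462198164	6.191068898	6.573569548	6.831443859	6.325106073	 7.01293408	7.544557788	6.331365112	7.294731222
gene_20	7.795562555	7.763294442	7.569028727	7.661400751	7.396287287	8.047272354	8.359822269	7.387736968	8.099808311	8.519432909
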