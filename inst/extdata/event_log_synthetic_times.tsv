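deployment_id	event_type	start_s	end_s	note
mn170612-30	nursing	3000	3015	descending
mn170612-30	nursing	8000	8031	horizontal
mn170612-30	nursing	14000	14018	horizontal
mn170612-30	lunge	3300	3310	
mn170612-30	dragging	8200	8215	
mn170612-30	lunge	14700	14710	
mn170612-30	poor_video	24000	24031	
mn170613-40	nursing	4000	4035	descending
mn170613-40	nursing	5000	5020	descending
mn170613-40	nursing	9000	9027	horizontal
mn170613-40	lunge	4200	4210	
mn170613-40	lunge	5100	5108	
mn170613-40	bottom_feeding	9040	9100	
mn170613-40	proximity	1000	1672	
mn170613-40	proximity	3900	4200	
mn170613-40	proximity	4900	5200	
mn170613-40	proximity	8900	9200	
mn170613-40	proximity	12000	12672	
mn180620-40	nursing	2000	2027	descending
mn180620-40	nursing	7000	7022	horizontal
mn180620-40	nursing	12000	12028	horizontal
mn180620-40	nursing	17000	17018	horizontal
mn180620-40	lunge	2747	2755	
mn180620-40	bottom_feeding	7100	7160	
mn180620-40	lunge	12100	12108	
mn180620-40	lunge	16900	16950	
mn180831-30	nursing	6000	6013	ascending
mn180831-30	lunge	6500	6510	
mn180831-30	poor_video	10000	10888	
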