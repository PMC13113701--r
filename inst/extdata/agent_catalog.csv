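code,display_name,is_carbapenem,is_antipseudomonal,is_anti_mrsa,aware_class,ddd_ref_g,unit_cost_eur
MEROPENEM,Meropenem,1,0,0,WATCH,3,24.00
IMIPENEM_CILASTATIN,Imipenem/cilastatin,1,0,0,WATCH,2,22.00
ERTAPENEM,Ertapenem,1,0,0,WATCH,1,30.00
PIPERACILLIN_TAZOBACTAM,Piperacillin/tazobactam,0,1,0,WATCH,14,15.00
CEFEPIME,Cefepime,0,1,0,WATCH,4,10.00
CEFTAZIDIME,Ceftazidime,0,1,0,WATCH,4,9.00
AZTREONAM,Aztreonam,0,1,0,RESERVE,4,40.00
VANCOMYCIN,Vancomycin,0,0,1,WATCH,2,12.00
LINEZOLID,Linezolid,0,0,1,RESERVE,1.2,45.00
TEICOPLANIN,Teicoplanin,0,0,1,WATCH,0.4,20.00
DAPTOMYCIN,Daptomycin,0,0,1,RESERVE,0.28,85.00
AMOXICILLIN,Amoxicillin,0,0,0,ACCESS,1.5,1.50
AMOXICILLIN_CLAVULANATE,Amoxicillin/clavulanate,0,0,0,ACCESS,3,3.00
AMPICILLIN_SULBACTAM,Ampicillin/sulbactam,0,0,0,ACCESS,6,6.00
CEFTRIAXONE,Ceftriaxone,0,0,0,WATCH,2,2.50
CEFUROXIME,Cefuroxime,0,0,0,WATCH,3,3.00
CIPROFLOXACIN,Ciprofloxacin,0,0,0,WATCH,1,2.00
LEVOFLOXACIN,Levofloxacin,0,0,0,WATCH,0.5,2.50
MOXIFLOXACIN,Moxifloxacin,0,0,0,WATCH,0.4,4.00
AZITHROMYCIN,Azithromycin,0,0,0,WATCH,0.3,2.00
CLARITHROMYCIN,Clarithromycin,0,0,0,WATCH,0.5,2.20
DOXYCYCLINE,Doxycycline,0,0,0,ACCESS,0.1,0.80
METRONIDAZOLE,Metronidazole,0,0,0,ACCESS,1.5,1.20
GENTAMICIN,Gentamicin,0,0,0,ACCESS,0.24,1.50
AMIKACIN,Amikacin,0,0,0,ACCESS,1,4.00
TRIMETHOPRIM_SULFAMETHOXAZOLE,Trimethoprim/sulfamethoxazole,0,0,0,ACCESS,1.92,1.00
CLINDAMYCIN,Clindamycin,0,0,0,ACCESS,1.8,3.50
NITROFURANTOIN,Nitrofurantoin,0,0,0,ACCESS,0.2,0.60
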