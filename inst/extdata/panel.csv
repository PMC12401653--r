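analyte,weighting,cal1,cal2,cal3,cal4,cal5,lloq,uloq,qc_low,qc_high,therapeutic_low,therapeutic_high,toxic_above,range_is_sum,sum_group,dual_status,working_solution,rt_min
Alprazolam,1/x2,50,125,250,375,500,50,500,60,400,5,50,100,FALSE,,FALSE,,
Amisulpride,1/x2,100,500,1000,1500,2000,100,2000,120,1600,100,400,640,FALSE,,FALSE,,
Amitriptyline,1/x2,100,500,1000,1500,2000,100,2000,120,1600,50,300,500,FALSE,,FALSE,,
Aripiprazole,equal,250,500,1000,1500,2000,250,2000,300,1600,100,350,1000,FALSE,,FALSE,,
Biperiden,1/x2,50,125,250,375,500,50,500,60,1600,1.0,6.5,13,FALSE,,FALSE,,
Bisoprolol,equal,100,500,1000,1500,2000,100,2000,120,1600,10,100,200,FALSE,,FALSE,,
Bromazepam,equal,1000,1500,2000,2500,3000,1000,3000,1200,2400,50,200,300,FALSE,,FALSE,,
Carbamazepine,1/x2,2500,5000,10000,15000,20000,2500,20000,3000,16000,2000,12000,10000,FALSE,,FALSE,,
Chlorprothixene,equal,250,500,1000,1500,2000,250,2000,300,1600,20,300,400,FALSE,,FALSE,,
Citalopram,1/x2,100,500,1000,1500,2000,100,2000,120,1600,50,110,220,FALSE,,FALSE,,
Clobazam,1/x2,100,500,1000,1500,2000,100,2000,120,1600,30,300,500,FALSE,,FALSE,,
Clozapine,1/x2,100,500,1000,1500,2000,100,2000,120,1600,100,600,600,FALSE,,FALSE,,
Codeine,1/x2,250,500,1000,1500,2000,250,2000,300,1600,30,250,500,FALSE,,FALSE,,
Desipramine,equal,250,500,1000,1500,2000,250,2000,300,1600,10,500,500,FALSE,,FALSE,,
Diazepam,1/x2,500,1000,1500,2000,2500,500,2500,600,2000,100,2500,5000,TRUE,diazepam,FALSE,,
Diazepam-M (nor-)/Nordiazepam,equal,750,1000,1500,2000,2500,750,2500,900,2000,120,800,1500,FALSE,diazepam,TRUE,,
Dihydrocodeine,1/x2,250,500,1000,1500,2000,250,2000,300,1600,30,250,500,FALSE,,FALSE,,
Diltiazem,1/x2,100,500,1000,1500,2000,100,2000,120,1600,30,250,800,FALSE,,FALSE,,
Diphenhydramine,1/x2,500,1000,1500,2000,2500,500,2500,600,2000,50,100,1000,FALSE,,FALSE,,
Doxepin,1/x2,100,500,1000,1500,2000,100,2000,120,1600,50,150,300,TRUE,doxepin,FALSE,,
Doxepin-M (nor-),equal,50,125,250,375,500,50,500,60,400,,,,FALSE,doxepin,FALSE,,
Doxylamine,1/x2,200,500,1000,1500,2000,200,2000,250,1600,50,200,1000,FALSE,,FALSE,,
Flupirtine,equal,1000,1500,2000,2500,3000,1000,3000,1200,2400,500,1500,3000,FALSE,,FALSE,,
Haloperidol,1/x2,50,125,250,375,500,50,500,60,400,1,17,50,FALSE,,FALSE,,
Hydromorphone,1/x2,50,125,250,375,500,50,500,60,400,5,30,100,FALSE,,FALSE,,
Imipramine,1/x2,250,500,1000,1500,2000,250,2000,300,1600,50,350,500,FALSE,,FALSE,,
Ketamine,1/x2,1000,2500,5000,7500,10000,1000,10000,1200,8000,100,6000,7000,FALSE,,FALSE,,
Levomepromazine,1/x2,200,500,1000,1500,2000,200,2000,250,1600,5,200,400,FALSE,,FALSE,,
Lorazepam,1/x2,500,1000,1500,2000,2500,500,2500,600,2000,20,250,300,FALSE,,FALSE,,
Maprotiline,1/x2,100,500,1000,1500,2000,100,2000,120,1600,75,130,500,FALSE,,FALSE,,
Melperone,1/x2,100,500,1000,1500,2000,100,2000,120,1600,30,100,200,FALSE,,FALSE,,
Methadone,1/x2,100,500,1000,1500,2000,100,2000,120,1600,50,600,600,FALSE,,FALSE,,
Metoclopramide,1/x2,100,500,1000,1500,2000,100,2000,120,1600,10,150,200,FALSE,,FALSE,,
Metoprolol,1/x2,100,500,1000,1500,2000,100,2000,120,1600,20,600,7800,FALSE,,FALSE,,
Mianserin,1/x2,50,125,250,375,500,50,500,60,400,15,70,250,FALSE,,FALSE,,
Midazolam,1/x2,100,500,1000,1500,2000,100,2000,120,1600,40,250,1000,FALSE,,FALSE,,
Mirtazapine,1/x2,150,500,1000,1500,2000,150,2000,180,1600,30,300,1000,FALSE,,FALSE,,
Moclobemide,equal,500,1500,2500,4000,5000,500,5000,600,4000,300,3000,2000,FALSE,,FALSE,,
Olanzapine,1/x2,50,125,250,375,500,50,500,60,400,1,80,100,FALSE,,FALSE,,
Opipramol,1/x2,100,500,1000,1500,2000,100,2000,120,1600,50,500,1000,FALSE,,FALSE,,
Oxazepam,equal,1000,1500,2000,2500,3000,1000,3000,1200,2400,200,1500,2000,FALSE,,FALSE,,
Oxcarbazepine,1/x2,2500,10000,20000,40000,80000,2500,80000,3000,65000,10000,35000,35000,FALSE,,FALSE,,
Oxycodone,1/x2,250,500,1000,1500,2000,250,2000,300,1600,5,100,200,FALSE,,FALSE,,
Paracetamol,1/x2,2500,30000,60000,90000,120000,2500,120000,3000,96000,5000,25000,100000,FALSE,,FALSE,,
Paroxetine,1/x2,50,125,250,375,500,50,500,60,400,2,65,400,FALSE,,FALSE,,
Perazine,1/x2,100,500,1000,1500,2000,100,2000,120,1600,10,230,460,FALSE,,FALSE,,
Pethidine,1/x2,500,1000,1500,2000,2500,500,2500,600,2000,100,800,1000,FALSE,,FALSE,,
Pethidine-M (nor-),equal,50,125,250,375,500,50,500,60,400,,,,FALSE,,FALSE,,
Pipamperone,equal,250,500,1000,1500,2000,250,2000,300,1600,100,400,500,FALSE,,FALSE,,
Promethazine,1/x2,100,500,1000,1500,2000,100,2000,120,1600,10,200,1000,FALSE,,FALSE,,
Prothipendyl,equal,50,125,250,375,500,50,500,60,400,30,80,500,FALSE,,FALSE,,
Quetiapine,1/x2,100,500,1000,1500,2000,100,2000,120,1600,100,500,1800,FALSE,,FALSE,,
Ramipril,1/x2,50,125,250,375,500,50,500,60,400,1,40,80,FALSE,,FALSE,,
Risperidone,1/x2,50,125,250,375,500,50,500,60,400,20,60,120,TRUE,risperidone,FALSE,,
Risperidone-M (9-hydroxy-)/Paliperidone,1/x2,100,500,1000,1500,2000,100,2000,120,1600,20,60,120,FALSE,risperidone,TRUE,,
Sertraline,equal,250,500,1000,1500,2000,250,2000,300,1600,10,500,300,FALSE,,FALSE,,
Sulpiride,equal,500,1000,1500,2000,2500,500,2500,600,2000,50,1000,1500,FALSE,,FALSE,,
Tapentadol,1/x2,100,500,1000,1500,2000,100,2000,120,1600,10,300,,FALSE,,FALSE,,
Temazepam,1/x2,500,1000,1500,2000,2500,500,2500,600,1600,20,900,1000,FALSE,,FALSE,,
Tilidine,1/x2,100,500,1000,1500,2000,100,2000,300,1600,50,300,,FALSE,,FALSE,,
Tilidine-M (nor-),1/x2,100,500,1000,1500,2000,100,2000,120,1600,,,,FALSE,,FALSE,,
Tramadol,1/x2,250,500,1000,1500,2000,250,2000,300,1600,100,1000,1000,FALSE,,FALSE,,
Tramadol-M (O-demethyl),1/x2,100,500,1000,1500,2000,100,2000,120,1600,,,,FALSE,,FALSE,,
Venlafaxine,1/x2,100,500,1000,1500,2000,100,2000,120,1600,100,400,1000,TRUE,venlafaxine,FALSE,,
Venlafaxine-M (O-demethyl),1/x2,100,500,1000,1500,2000,100,2000,120,1600,,,,FALSE,venlafaxine,FALSE,,
Verapamil,equal,100,500,1000,1500,2000,100,2000,120,1600,10,400,1000,FALSE,,FALSE,,
Zolpidem,1/x2,100,500,1000,1500,2000,100,2000,120,1600,80,200,500,FALSE,,FALSE,,
Zopiclone,equal,100,500,1000,1500,2000,100,2000,120,1600,10,120,150,FALSE,,FALSE,,
Zuclopenthixol,1/x2,50,125,250,375,500,50,500,60,400,4,100,100,FALSE,,FALSE,,
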