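sample_id,patient_id,group,grade,lesion_order,tobacco
1a,1,PL,Focal keratosis,1,yes
1b,1,PL,Mild squamous hyperplasia,2,yes
1c,1,PL,Carcinoma in situ,3,yes
1d,1,OSCC,Invasive moderately differentiated OSCC,4,yes
4a,4,PL,Severe squamous dysplasia,1,no
4b,4,PL,Mild squamous dysplasia,2,no
4c,4,PL,Severe squamous dysplasia,3,no
4d,4,PL,Severe dysplasia + SCC micro foci,4,no
4e,4,OSCC,Invasive moderately differentiated OSCC,5,no
5a,5,PL,Keratosis,1,yes
5b,5,PL,Moderate dysplasia,2,yes
5c,5,PL,Severe dysplasia,3,yes
5d,5,PL,Mild dysplasia,4,yes
5e,5,OSCC,Invasive OSCC,5,yes
10a,10,PL,Keratosis,1,yes
10b,10,PL,Moderate dysplasia,2,yes
10c,10,PL,Mild dysplasia,3,yes
10d,10,PL,Moderate + Severe dysplasia,4,yes
10e,10,PL,Severe dysplasia + carcinoma in situ,5,yes
10f,10,OSCC,Invasive moderately differentiated OSCC,6,yes
15a,15,PL,Mild dysplasia,1,yes
15b,15,PL,Moderate dysplasia,2,yes
15c,15,PL,Keratosis mild atypia,3,yes
15d,15,OSCC,Moderately differentiated OSCC,4,yes
NP1,NP1,NPL,Mild dysplasia,1,no
NP2,NP2,NPL,Mild dysplasia,1,no
NP3,NP3,NPL,Moderate dysplasia,1,no
NP4,NP4,NPL,Moderate dysplasia,1,no
NP5,NP5,NPL,Severe dysplasia,1,no
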