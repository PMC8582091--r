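column,required,type,range,units,description
id,yes,text,,,unique anonymized participant code
age,yes,numeric,65-,years,age at assessment
sex,yes,text,,,"F/M/female/male, case-insensitive"
falls_12m,yes,integer,0-,count,self-reported falls in the previous 12 months
chronic_diseases,no,integer,0-,count,number of chronic comorbidities
physical_impairments,no,integer,0-6,count,"reported impairments (dizziness, incontinence, vision, feet, hearing, balance loss)"
cognitive,no,numeric,0-30,score,Mini-Mental State Examination total
physical_function,no,numeric,0-24,score,Composite Physical Function scale total
balance,no,numeric,0-40,score,Fullerton Advanced Balance scale total
fear_of_falling,no,numeric,16-64,score,Falls Efficacy Scale - International total
affordance_error,no,numeric,0-,cm,absolute error |real - estimated| stepping-forward distance
gait,no,numeric,0-12,score,Tinetti performance-oriented mobility assessment gait section
physical_activity,no,numeric,0-,MET-min/week,IPAQ short-form weekly metabolic expenditure
environmental_hazards,no,integer,0-34,count,environmental hazards identified in the dwelling
weight,optional,numeric,,kg,body mass
height,optional,numeric,,cm,standing height
waist,optional,numeric,,cm,waist circumference
bmi,optional,numeric,,kg/m2,body mass index; must equal weight/(height in m)^2 when all present
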