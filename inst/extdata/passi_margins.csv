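variable,level,count,pct
smoking,Smoker,51696,27.9
smoking,Non-smoker,133923,72.1
age,18-29,33450,18.0
age,30-39,38660,20.8
age,40-49,44193,23.8
age,50-59,35646,19.2
age,60-69,33670,18.2
sex,Male,91160,49.1
sex,Female,94459,50.9
marital,Married,112853,60.8
marital,Single,57959,31.2
marital,Widowed or divorced,14807,8.0
education,University or higher,24700,13.3
education,High school,82324,44.4
education,Middle school,58063,31.3
education,Primary school or less,20532,11.0
income,High,87989,47.4
income,Medium,74159,40.0
income,Low,23471,12.6
work,Works,107648,58.0
work,Does not work,77971,42.0
region,North,92741,50.0
region,Central,45142,24.3
region,South,47736,25.7
physical,Active,61357,33.1
physical,Partially active,70800,38.1
physical,Sedentary,53462,28.8
alcohol,High risk drinker,18852,10.2
alcohol,Low risk drinker,52838,28.4
alcohol,Non-drinker,113929,61.4
depression,Not depressed,173416,93.4
depression,Depressed,12203,6.6
year,2008,37205,20.0
year,2009,38690,20.8
year,2010,35896,19.2
year,2011,36825,19.8
year,2012,37003,20.0
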