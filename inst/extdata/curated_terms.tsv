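term	category
suicide attempt	risk
thoughts of suicide	risk
suicidal ideation	risk
feeling suicidal	risk
self harm	risk
cutting	risk
overdose	risk
hopelessness	risk
depressed mood	risk
severe depression	risk
major depression	risk
PTSD	risk
trauma history	risk
psychosis	risk
bipolar	risk
substance abuse	risk
alcohol use	risk
cannabis use	risk
impulsivity	risk
aggression	risk
family conflict	risk
bullying	risk
social isolation	risk
insomnia	risk
anxiety	risk
panic attacks	risk
eating disorder	risk
prior hospitalization	risk
medication noncompliance	risk
running away	risk
foster care	risk
pain	risk
grief	risk
firearm access	risk
family support	protective
social support	protective
safety plan	protective
coping skills	protective
therapy	protective
counseling	protective
medication adherence	protective
school engagement	protective
academic achievement	protective
peer support	protective
close friends	protective
religious involvement	protective
future plans	protective
exercise	protective
hobbies	protective
supportive family	protective
good grades	protective
attends church	protective
future orientation	protective
problem solving skills	protective
emotional regulation	protective
help seeking	protective
mentorship	protective
sports participation	protective
community involvement	protective
stable housing	protective
optimism	protective
resilience	protective
self esteem	protective
sense of belonging	protective
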