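raw_name,category
fentanyl,fentanyl
acetyl fentanyl,fentanyl
acetylfentanyl,fentanyl
furanyl fentanyl,fentanyl
carfentanil,fentanyl
cocaine,cocaine
crack cocaine,cocaine
cocaine base,cocaine
heroin,heroin
prescription_opioids,prescription_opioids
oxycodone,prescription_opioids
hydrocodone,prescription_opioids
oxymorphone,prescription_opioids
hydromorphone,prescription_opioids
morphine,prescription_opioids
codeine,prescription_opioids
tramadol,prescription_opioids
methadone,prescription_opioids
buprenorphine,prescription_opioids
amphetamines,amphetamines
amphetamine,amphetamines
methamphetamine,amphetamines
benzodiazepines,benzodiazepines
alprazolam,benzodiazepines
diazepam,benzodiazepines
clonazepam,benzodiazepines
lorazepam,benzodiazepines
temazepam,benzodiazepines
midazolam,benzodiazepines
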