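code,description
F11.10,opioid abuse uncomplicated
F11.120,opioid abuse with intoxication uncomplicated
F11.20,opioid dependence uncomplicated
F11.21,opioid dependence in remission
F11.220,opioid dependence with intoxication uncomplicated
F11.23,opioid dependence with withdrawal
F11.90,opioid use unspecified uncomplicated
F11.920,opioid use unspecified with intoxication
F11.93,opioid use unspecified with withdrawal
T40.0X1A,poisoning by opium accidental initial encounter
T40.1X1A,poisoning by heroin accidental initial encounter
T40.2X1A,poisoning by other opioids accidental initial encounter
T40.3X1A,poisoning by methadone accidental initial encounter
T40.4X1A,poisoning by synthetic narcotics accidental initial encounter
T40.601A,poisoning by unspecified narcotics accidental initial encounter
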