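>seed01 synthetic PSPG box seed
WAPQVEVLAHPAVGGFVTHCGWNSTLESISAGVPMVAWPLYAEQ
>seed02 synthetic PSPG box seed
WAPQVLVLLHPAVGGFVTHCGWNSTLESLSAGVPMLAWPLYAEQ
>seed03 synthetic PSPG box seed
WVPQVVVLAHVAVGVFVTHCGWNSTLEVISAGVPMVAWPLYAEQ
>seed04 synthetic PSPG box seed
WAPQAEVLAHPAVGAFATHCGWNSALESASAGVAAVAWPLYAEQ
>seed05 synthetic PSPG box seed
WAPQVEVLAHKAVGGFVKHCGWNSTLESIKKGVPMKAWKKYAEQ
>seed06 synthetic PSPG box seed
WSPQVEVLSHPASGGFVTHCGWNSTLESISSGVPSVAWPLYAEQ
>seed07 synthetic PSPG box seed
WAPQVEVLAHPAVAAFVTHCGWNSALESASAGVPMVAWPLYAEQ
>seed08 synthetic PSPG box seed
WAPQMEVLAHMAVGGFMTHCGWNSTLESISMGVPMVMWPMYAEQ
>seed09 synthetic PSPG box seed
WAPQVEILIIPAVGGFVTHCGWNSTIESISAGVPMVIWPIIAEQ
>seed10 synthetic PSPG box seed
WAPQLLVLLLPAVGGFLTHCGWNSTLESLSAGVPMVAWPLLALQ
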