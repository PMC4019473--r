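tests:
  cta:
    sens: 0.96
    spec: 0.99
  ncct:
    sens: 0.95
    spec: 0.35
  dsa:
    sens: 1.0
    spec: 1.0
mrs:
  primary:
    mrs01: 0.08
    mrs23: 0.23
    mrs45: 0.4
    mrs6: 0.29
  secondary:
    mrs01: 0.694
    mrs23: 0.224
    mrs45: 0.035
    mrs6: 0.047
epi:
  lesion_prevalence: 0.45
  rebleed_primary: 0.0208
  rebleed_secondary_untreated: 0.0392
  rr_after_repair: 0.35
costs:
  cta: 425.0
  dsa: 1100.0
  hosp_secondary: 85400.0
  hosp_primary: 25300.0
  ltc_mrs23: 8438.0
  ltc_mrs45_year1: 71428.0
  ltc_mrs45_later: 37140.0
utilities:
  mrs01: 0.9
  mrs23: 0.75
  mrs45: 0.25
  dead: 0.0
settings:
  initial_age: 40.0
  max_age: 100.0
  discount_rate: 0.03
  wtp: 100000.0
  cycle_length: 1.0
  half_cycle_correction: no
  background_mortality: yes
  missed_lesion_mrs: secondary
  event_cycle_accrual: state
life_table:
  age:
  - 0
  - 1
  - 2
  - 3
  - 4
  - 5
  - 6
  - 7
  - 8
  - 9
  - 10
  - 11
  - 12
  - 13
  - 14
  - 15
  - 16
  - 17
  - 18
  - 19
  - 20
  - 21
  - 22
  - 23
  - 24
  - 25
  - 26
  - 27
  - 28
  - 29
  - 30
  - 31
  - 32
  - 33
  - 34
  - 35
  - 36
  - 37
  - 38
  - 39
  - 40
  - 41
  - 42
  - 43
  - 44
  - 45
  - 46
  - 47
  - 48
  - 49
  - 50
  - 51
  - 52
  - 53
  - 54
  - 55
  - 56
  - 57
  - 58
  - 59
  - 60
  - 61
  - 62
  - 63
  - 64
  - 65
  - 66
  - 67
  - 68
  - 69
  - 70
  - 71
  - 72
  - 73
  - 74
  - 75
  - 76
  - 77
  - 78
  - 79
  - 80
  - 81
  - 82
  - 83
  - 84
  - 85
  - 86
  - 87
  - 88
  - 89
  - 90
  - 91
  - 92
  - 93
  - 94
  - 95
  - 96
  - 97
  - 98
  - 99
  - 100
  - 101
  - 102
  - 103
  - 104
  - 105
  - 106
  - 107
  - 108
  - 109
  - 110
  qx:
  - 0.00053
  - 0.0005327
  - 0.000535643
  - 0.00053885087
  - 0.0005423474483
  - 0.000546158718647
  - 0.000550313003325
  - 0.000554841173625
  - 0.000559776879251
  - 0.000565156798383
  - 0.000571020910238
  - 0.000577412792159
  - 0.000584379943453
  - 0.000591974138364
  - 0.000600251810817
  - 0.000609274473791
  - 0.000619109176432
  - 0.000629829002311
  - 0.000641513612519
  - 0.000654249837645
  - 0.000668132323033
  - 0.000683264232106
  - 0.000699758012996
  - 0.000717736234166
  - 0.00073733249524
  - 0.000758692419812
  - 0.000781974737595
  - 0.000807352463979
  - 0.000835014185737
  - 0.000865165462453
  - 0.000898030354074
  - 0.000933853085941
  - 0.000972899863675
  - 0.001015460851406
  - 0.001061852328033
  - 0.001112419037555
  - 0.001167536750935
  - 0.00122761505852
  - 0.001293100413786
  - 0.001364479451027
  - 0.00144228260162
  - 0.001527088035765
  - 0.001619525958984
  - 0.001720283295293
  - 0.001830108791869
  - 0.001949818583138
  - 0.00208030225562
  - 0.002222529458626
  - 0.002377557109902
  - 0.002546537249793
  - 0.002730725602275
  - 0.002931490906479
  - 0.003150325088062
  - 0.003388854345988
  - 0.003648851237127
  - 0.003932247848468
  - 0.004241150154831
  - 0.004577853668765
  - 0.004944860498954
  - 0.00534489794386
  - 0.005780938758807
  - 0.0062562232471
  - 0.006774283339339
  - 0.00733896883988
  - 0.007954476035469
  - 0.008625378878661
  - 0.009356662977741
  - 0.010153762645737
  - 0.011022601283854
  - 0.0119696353994
  - 0.013001902585346
  - 0.014127073818028
  - 0.01535351046165
  - 0.016690326403199
  - 0.018147455779486
  - 0.01973572679964
  - 0.021466942211608
  - 0.023353967010653
  - 0.025410824041611
  - 0.027652798205356
  - 0.030096550043838
  - 0.032760239547784
  - 0.035663661107084
  - 0.038828390606722
  - 0.042277945761327
  - 0.046037960879847
  - 0.050136377359033
  - 0.054603651321346
  - 0.059472979940267
  - 0.064780548134891
  - 0.070565797467031
  - 0.076871719239064
  - 0.083745173970579
  - 0.091237239627932
  - 0.099403591194446
  - 0.108304914401946
  - 0.118007356698121
  - 0.128583018800952
  - 0.140110490493037
  - 0.152675434637411
  - 0.166371223754778
  - 0.181299633892708
  - 0.197571600943051
  - 0.215308045027926
  - 0.234640769080439
  - 0.255713438297679
  - 0.27868264774447
  - 0.303719086041472
  - 0.331008803785205
  - 0.360754596125873
  - 1.0
prevalence_lookup:
  age_lo:
  - 0
  - 11
  - 21
  - 31
  - 41
  - 51
  - 61
  - 71
  - 81
  age_hi:
  - 10.0
  - 20.0
  - 30.0
  - 40.0
  - 50.0
  - 60.0
  - 70.0
  - 80.0
  - 110.0
  prevalence:
  - 0.6
  - 0.6
  - 0.55
  - 0.45
  - 0.08
  - 0.3
  - 0.25
  - 0.2
  - 0.2
psa:
  cta_sens:
    family: beta
    base: 0.96
    low: 0.8
    high: 1.0
  cta_spec:
    family: beta
    base: 0.99
    low: 0.8
    high: 1.0
  ncct_sens:
    family: beta
    base: 0.95
    low: 0.7
    high: 1.0
  ncct_spec:
    family: beta
    base: 0.35
    low: 0.0
    high: 0.6
  mrs_primary:
    family: dirichlet
    base:
      mrs01: 0.08
      mrs23: 0.23
      mrs45: 0.4
      mrs6: 0.29
    low:
    - 0.0
    - 0.0
    - 0.3
    - 0.15
    high:
    - 0.18
    - 0.5
    - 0.5
    - 0.45
    alpha0: 100.0
  mrs_secondary:
    family: dirichlet
    base:
      mrs01: 0.694
      mrs23: 0.224
      mrs45: 0.035
      mrs6: 0.047
    low:
    - 0.3
    - 0.0
    - 0.0
    - 0.0
    high:
    - 1.0
    - 0.5
    - 0.2
    - 0.2
    alpha0: 100.0
  rebleed_primary:
    family: beta
    base: 0.0208
    low: 0.0
    high: 0.06
  rebleed_secondary_untreated:
    family: beta
    base: 0.0392
    low: 0.0
    high: 0.1
  rr_after_repair:
    family: lognormal
    base: 0.35
    low: 0.0
    high: 2.0
  cost_cta:
    family: normal
    base: 425.0
    low: 100.0
    high: 1500.0
  cost_dsa:
    family: normal
    base: 1100.0
    low: 450.0
    high: 2000.0
  hosp_secondary:
    family: lognormal
    base: 85400.0
    low: 10000.0
    high: 300000.0
  hosp_primary:
    family: lognormal
    base: 25300.0
    low: 3000.0
    high: 120000.0
  ltc_mrs23:
    family: lognormal
    base: 8438.0
    low: 0.0
    high: 20000.0
  ltc_mrs45_year1:
    family: lognormal
    base: 71428.0
    low: 30000.0
    high: 150000.0
  ltc_mrs45_later:
    family: lognormal
    base: 37140.0
    low: 10000.0
    high: 90000.0
  u_mrs01:
    family: beta
    base: 0.9
    low: 0.2
    high: 1.0
  u_mrs23:
    family: beta
    base: 0.75
    low: 0.0
    high: 1.0
  u_mrs45:
    family: beta
    base: 0.25
    low: -0.1
    high: 1.0
  initial_age:
    family: normal
    base: 40.0
    low: 10.0
    high: 80.0
    sd: 12.5

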