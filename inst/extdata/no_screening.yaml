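meta:
  name: no_screening
  currency: 2013-14 AUD
ages:
  start_age: 3
  education_start_age: 5
  discharge_age: 9
  income_loss_start_age: 16
  adult_age: 18
  screening_stop_age: 18
  terminal_age: 50
discount_rate: 0.05
strategies:
- DeadlyEars
- MTESS
transitions:
  p_screen:
    DeadlyEars: 0.0
    MTESS: 0.0
  p_false_negative: 0.05
  p_true_negative: 0.9
  p_treat_if_detected: 0.86
  p_medical_vs_surgical: 0.8
  p_treat_failure: 0.1
  p_progress_untreated: 0.1
  p_aid_child: 0.05
  p_aid_adult: 0.35
  p_gp_detection: 0.219
  p_ear_by_age:
    age_from:
    - 3
    - 15
    age_to:
    - 14
    - 50
    p:
    - 0.02677028955
    - 0.008979025267
  mortality_by_age:
    age:
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
    q:
    - 0.000297864571
    - 0.000320101753
    - 0.000343999059
    - 0.000369680428
    - 0.000397279047
    - 0.000426938051
    - 0.000458811258
    - 0.000493063971
    - 0.000529873831
    - 0.000569431744
    - 0.000611942867
    - 0.000657627672
    - 0.000706723092
    - 0.000759483748
    - 0.000816183268
    - 0.000877115711
    - 0.000942597086
    - 0.001012966996
    - 0.001088590396
    - 0.001169859486
    - 0.001257195749
    - 0.00135105213
    - 0.001451915391
    - 0.001560308635
    - 0.001676794013
    - 0.001801975646
    - 0.001936502758
    - 0.002081073038
    - 0.002236436262
    - 0.00240339818
    - 0.002582824698
    - 0.002775646365
    - 0.002982863199
    - 0.003205549878
    - 0.003444861307
    - 0.003702038613
    - 0.003978415579
    - 0.004275425563
    - 0.00459460893
    - 0.00493762104
    - 0.005306240838
    - 0.005702380073
    - 0.006128093219
    - 0.006585588127
    - 0.007077237475
    - 0.007605591073
    - 0.008173389092
    - 0.008783576266
costs:
  screen_cost:
    DeadlyEars: 88.0
    MTESS: 117.0
  medical_child: 82.0
  medical_adult: 91.0
  surgical_child: 2369.0
  surgical_adult: 6021.0
  hearing_aid_annual: 1606.0
  cochlear_annual: 3152.0
  education_annual: 7116.0
  income_loss_annual: 6681.0
aid_split:
  child:
    non_cochlear: 1.0
    cochlear: 0.0
  adult:
    non_cochlear: 1.0
    cochlear: 0.0
utilities:
  u_healthy_child: 1.0
  u_healthy_adult: 0.9
  u_hearing_loss: 0.677
  u_ear_child: 0.839
  u_ear_adult: 0.789
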