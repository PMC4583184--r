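{
  "meta": {
    "name": "base_case",
    "currency": "2013-14 AUD"
  },
  "ages": {
    "start_age": 3,
    "education_start_age": 5,
    "discharge_age": 9,
    "income_loss_start_age": 16,
    "adult_age": 18,
    "screening_stop_age": 18,
    "terminal_age": 50
  },
  "discount_rate": 0.05,
  "strategies": ["DeadlyEars", "MTESS"],
  "transitions": {
    "p_screen": {
      "DeadlyEars": 0.39,
      "MTESS": 0.8
    },
    "p_false_negative": 0.05,
    "p_true_negative": 0.9,
    "p_treat_if_detected": 0.86,
    "p_medical_vs_surgical": 0.8,
    "p_treat_failure": 0.1,
    "p_progress_untreated": 0.1,
    "p_aid_child": 0.05,
    "p_aid_adult": 0.35,
    "p_gp_detection": 0.219,
    "p_ear_by_age": {
      "age_from": [3, 15],
      "age_to": [14, 50],
      "p": [0.02677028954977, 0.00897902526689]
    },
    "mortality_by_age": {
      "age": [3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33, 34, 35, 36, 37, 38, 39, 40, 41, 42, 43, 44, 45, 46, 47, 48, 49, 50],
      "q": [0.000297864570960161, 0.000320101752989612, 0.000343999059494482, 0.00036968042763867, 0.000397279047157693, 0.000426938051112595, 0.00045881125821234, 0.000493063970554533, 0.000529873830921752, 0.000569431744079626, 0.000611942866854748, 0.000657627672127186, 0.000706723092255726, 0.000759483747865919, 0.000816183268373724, 0.000877115711093292, 0.000942597086288739, 0.00101296699607917, 0.00108859039569675, 0.00116985948623205, 0.00125719574868303, 0.00135105212985652, 0.00145191539145911, 0.00156030863456003, 0.00167679401251885, 0.00180197564644759, 0.00193650275832775, 0.00208107303803123, 0.00223643626170738, 0.00240339818030193, 0.00258282469837471, 0.00277564636488839, 0.00298286319925861, 0.00320554987769455, 0.00344486130672755, 0.00370203861283342, 0.00397841557921202, 0.00427542556310693, 0.0045946089295399, 0.00493762104001337, 0.00530624083761229, 0.0057023800730297, 0.00612809321936436, 0.00658558812711113, 0.00707723747460318, 0.007605591073291, 0.0081733890916762, 0.00878357626648271]
    }
  },
  "costs": {
    "screen_cost": {
      "DeadlyEars": 88,
      "MTESS": 117
    },
    "medical_child": 82,
    "medical_adult": 91,
    "surgical_child": 2369,
    "surgical_adult": 6021,
    "hearing_aid_annual": 1606,
    "cochlear_annual": 3152,
    "education_annual": 7116,
    "income_loss_annual": 6681
  },
  "aid_split": {
    "child": {
      "non_cochlear": 1,
      "cochlear": 0
    },
    "adult": {
      "non_cochlear": 1,
      "cochlear": 0
    }
  },
  "utilities": {
    "u_healthy_child": 1,
    "u_healthy_adult": 0.9,
    "u_hearing_loss": 0.677,
    "u_ear_child": 0.839,
    "u_ear_adult": 0.789
  }
}
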