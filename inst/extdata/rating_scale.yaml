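# Qualitative influence rating scale, version 1.
# Each metric kind lists the inclusive upper bounds of the 0.5..2.5 score
# bins; values above the last bound score 3 ("Large"). An exact zero (to
# within zero_tolerance, in the metric's own unit) scores 0 ("None").
# Scores: 0 None, 0.5 Negligible, 1 Small, 1.5 Small-Medium, 2 Medium,
# 2.5 Medium-Large, 3 Large.
version: 1
zero_tolerance: 1.0e-12
scores: [0.5, 1, 1.5, 2, 2.5]
top_score: 3
uppers:
  convergence_pct: [1, 5, 10, 20, 40]   # % difference in last converged step
  valgus_rmse:     [0.2, 0.5, 0.9, 1.4, 2]   # degrees
  pressure_pct:    [1, 5, 10, 20, 40]   # % difference in peak pressure
  location_mm:     [0.2, 0.5, 1.25, 2.5, 4]  # mm distance between peaks
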