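# Admissible contact-coverage band per disorder x World Bank income group.
# A null bound means no threshold is applied on that side.
#
# RECONSTRUCTED, EDITABLE: these defaults are plausible reconstructions
# anchored on published survey-based 12-month service-use figures (lower
# bounds for psychosis from the lowest severe-disorder coverage observed
# per income group; upper bounds for depression from the highest; a single
# global upper bound for bipolar spectrum treatment). They are
# configuration, not measured values -- replace them with your own table
# via read_thresholds().
psychosis:
  low:          {lower: 0.005, upper: null}
  lower_middle: {lower: 0.010, upper: null}
  upper_middle: {lower: 0.015, upper: null}
  high:         {lower: 0.020, upper: null}
bipolar:
  low:          {lower: null, upper: 0.229}
  lower_middle: {lower: null, upper: 0.229}
  upper_middle: {lower: null, upper: 0.229}
  high:         {lower: null, upper: 0.229}
depression:
  low:          {lower: null, upper: 0.182}
  lower_middle: {lower: null, upper: 0.182}
  upper_middle: {lower: null, upper: 0.311}
  high:         {lower: null, upper: 0.506}
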