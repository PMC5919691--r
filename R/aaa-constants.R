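# Zone order is fixed across the package: proliferating, pre-hypertrophic,
# upper and lower hypertrophic.  Phase clusters I-IV peak in these zones
# in order.
ZONES <- c("PZ", "PHZ", "UHZ", "LHZ")
CLUSTER_IDS <- c("I", "II", "III", "IV")
CLUSTER_ZONE <- stats::setNames(ZONES, CLUSTER_IDS)
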