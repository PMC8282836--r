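# Builders for small in-code fixtures.

make_pop <- function(cfp, ifp = cfp, ofp = cfp,
                     topology = "CONSTANT", flp_ng = 35, shrna_ng = 5,
                     dox_nM = 0, time_h = 48, replicate = 1L) {
  sample_population(data.frame(cfp = cfp, ifp = ifp, ofp = ofp),
                    condition(topology, flp_ng, shrna_ng, dox_nM,
                              time_h, replicate))
}

# two-condition table in the canonical schema
make_table <- function() {
  data.frame(
    topology = rep(c("CONSTANT", "CONSTANT"), each = 3),
    flp_ng = 35, shrna_ng = 5,
    dox_nM = rep(c(0, 225), each = 3),
    time_h = 48, replicate = 1L,
    cfp = c(110.5, 220.25, 330.125, 1001, 2002, 3003) / 3,
    ifp = c(10, 20, 30, 40, 50, 60) * pi,
    ofp = c(1, 2, 3, 4, 5, 6) * exp(1))
}

# brute-force AUC oracle: pairwise concordance with half credit for ties
auc_bruteforce <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  sum(cmp) / (length(pos) * length(neg))
}
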