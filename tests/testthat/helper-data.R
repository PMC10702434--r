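# quick constructor for measurement rows
mk_meas <- function(sample_id, compartment, congener, value = NA_real_,
                    status = "detected", detection_limit = NA_real_) {
  data.frame(sample_id = sample_id, compartment = compartment,
             congener = congener, value = value, status = status,
             detection_limit = detection_limit, stringsAsFactors = FALSE)
}

# a one-sample, two-congener liver record with the given PFOS/PFNA values
mk_sample <- function(id, pfos, pfna, compartment = "liver") {
  rbind(mk_meas(id, compartment, "PFOS", pfos),
        mk_meas(id, compartment, "PFNA", pfna))
}

# fixture mean for one compartment x congener
t1_mean <- function(compartment, congener,
                    t1 = pfasweb::table1_summaries()) {
  t1$mean[t1$compartment == compartment & t1$congener == congener]
}
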