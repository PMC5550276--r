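# Shared fixtures built in code.

# small informative test PWM (width 5, used for enumeration oracles)
test_pwm5 <- function(bg = patser_background(0.28, 0.18)) {
  m <- rbind(c(0.85, 0.05, 0.05, 0.05),
             c(0.05, 0.85, 0.05, 0.05),
             c(0.05, 0.05, 0.85, 0.05),
             c(0.05, 0.05, 0.05, 0.85),
             c(0.70, 0.10, 0.10, 0.10))
  new_pwm("toy5", m, background = bg)
}

packaged_motifs <- function() {
  read_meme(system.file("extdata", "motifs_synthetic.meme",
                        package = "crmdiverge"))
}

# small, fast simulation used across tests
small_sim <- function(seed = 11, n = 150, ...) {
  simulate_two_species(sim_config(n_crms = n, seed = seed, ...))
}

random_dna <- function(n, len, bg = c(0.28, 0.22, 0.22, 0.28),
                       seed = NULL) {
  gen <- function() vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE, prob = bg),
          collapse = ""), "")
  if (is.null(seed)) gen() else crmdiverge:::with_seed(seed, gen())
}
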