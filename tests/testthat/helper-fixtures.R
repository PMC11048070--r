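# Shared fixtures and independent oracles.

# random feasible method-1 + composite targets
random_targets <- function() {
  list(adh = runif(1, 10, 50), pdh = runif(1, 10, 50),
       aspo = runif(1, -15, 15), pspo = runif(1, -15, 15),
       epwr = runif(1, 0.9, 1.1), hw_ratio = runif(1, 0.45, 0.8))
}

random_level <- function() metrics_to_landmarks(random_targets())

# apply a rigid motion + uniform scale to every landmark of a level
transform_level <- function(level, theta = 0, shift = c(0, 0), scale = 1) {
  R <- scale * rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  tf <- function(v) {
    for (nm in c("as_pt", "ps_pt", "ai_pt", "pi_pt"))
      v[[nm]] <- drop(R %*% v[[nm]]) + shift
    v
  }
  level$sup <- tf(level$sup)
  level$inf <- tf(level$inf)
  level
}

# mirror about a vertical axis with anterior/posterior corner-role swap
mirror_level <- function(level) {
  mir <- function(v) {
    flip <- function(p) c(-p[1], p[2])
    vertebra_landmarks(v$label,
                       as_pt = flip(v$ps_pt), ps_pt = flip(v$as_pt),
                       ai_pt = flip(v$pi_pt), pi_pt = flip(v$ai_pt),
                       check_frame = FALSE)
  }
  spine_level(mir(level$sup), mir(level$inf), level$osteo_flag)
}

# independent O(n^2) oracles for the robust estimators (naive double loops)
hl_bruteforce <- function(x) {
  n <- length(x); w <- c()
  for (i in 1:n) for (j in i:n) w <- c(w, (x[i] + x[j]) / 2)
  median(w)
}

qn_bruteforce <- function(x) {
  n <- length(x); d <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) d <- c(d, abs(x[i] - x[j]))
  h <- floor(n / 2) + 1
  k <- choose(h, 2)
  dn <- if (n <= 9) c(NA, 0.399, 0.994, 0.512, 0.844, 0.611, 0.857, 0.669, 0.872)[n]
        else if (n %% 2 == 1) n / (n + 1.4) else n / (n + 3.8)
  2.2219 * dn * sort(d)[k]
}

# small landmark population files on disk for reader tests
write_demo_files <- function(dir) {
  cfg <- population_config(n_subjects = 4, seed = 7)
  pop <- sample_population(cfg)
  write_landmarks(pop$subjects, dir)
  pop
}
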