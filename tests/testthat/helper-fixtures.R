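# Shared fixtures: tiny record sets, a synthetic reference-rate table with
# smooth age gradients, and an independent microsimulation oracle for the
# competing-risk engine.

make_record <- function(person_id, sex = "female", age = 70,
                        event_date = "2011-06-01", icd10 = "S72.0",
                        energy = "low", resident = TRUE) {
  data.frame(person_id = person_id, sex = sex, age = age,
             event_date = as.Date(event_date), icd10 = icd10,
             energy = energy, resident = resident, stringsAsFactors = FALSE)
}

tiny_population <- function(period_years = 2) {
  population_table(data.frame(
    sex = rep(c("female", "male"), each = 3),
    age_low = rep(c(40, 50, 60), 2),
    age_high = rep(c(50, 60, Inf), 2),
    count = c(10000, 8000, 6000, 9000, 7000, 5000)), period_years)
}

# smooth synthetic "Malmo-like" reference: hip rising exponentially with age,
# forearm humped, humerus rising gently; labelled synthetic throughout
synthetic_reference <- function(banding = default_banding()) {
  mid <- ifelse(is.infinite(banding$age_high), banding$age_low + 5,
                (banding$age_low + banding$age_high) / 2)
  rows <- list()
  for (s in c("female", "male")) {
    k <- if (s == "female") 1 else 0.6
    hip <- 12 * exp(0.09 * (mid - 40)) * k
    forearm <- (180 + 9 * (mid - 40) - 0.07 * (mid - 40)^2) * k
    humerus <- (60 + 4 * (mid - 40)) * k
    rows[[s]] <- data.frame(
      sex = s, age_low = rep(banding$age_low, 3),
      age_high = rep(banding$age_high, 3),
      site = rep(c("hip", "forearm", "humerus"), each = nrow(banding)),
      rate = c(hip, forearm, humerus), source = "synthetic-reference")
  }
  reference_rates(do.call(rbind, rows))
}

# event-time microsimulation under piecewise-constant annual hazards:
# independent of the engine's closed-form year sum
microsim_competing <- function(schedule, start_age, horizon, n, seed) {
  set.seed(seed)
  idx <- match(seq(start_age, length.out = horizon), schedule$ages)
  stopifnot(!anyNA(idx))
  status <- integer(n) # 0 event-free, 1 fracture first, 2 death first
  for (k in idx) {
    alive <- which(status == 0L)
    if (!length(alive)) break
    hf <- schedule$fracture_hazard[k]
    hd <- schedule$death_hazard[k]
    tf <- if (hf > 0) stats::rexp(length(alive), hf) else
      rep(Inf, length(alive))
    td <- if (hd > 0) stats::rexp(length(alive), hd) else
      rep(Inf, length(alive))
    ev <- pmin(tf, td) < 1
    status[alive[ev & tf <= td]] <- 1L
    status[alive[ev & td < tf]] <- 2L
  }
  list(p_fracture = mean(status == 1L), p_death = mean(status == 2L),
       p_free = mean(status == 0L), n = n)
}

# random step schedule over [40, 110)
random_schedule <- function(seed, max_hf = 0.05, max_hd = 0.15) {
  set.seed(seed)
  ages <- 40:109
  n_steps <- sample(2:6, 1)
  edges <- sort(sample(45:100, n_steps - 1))
  step_of <- findInterval(ages, c(40, edges))
  structure(list(sex = "female", site = "hip", ages = ages,
                 fracture_hazard = stats::runif(n_steps, 0, max_hf)[step_of],
                 death_hazard = stats::runif(n_steps, 0, max_hd)[step_of]),
            class = "hazard_schedule")
}
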