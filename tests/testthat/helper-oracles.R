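# Independent brute-force oracles used to validate the implementation.
# These deliberately use naive day-by-day / enumeration algorithms, not the
# interval arithmetic of the package.

# set of covered integer days for one person's fills
brute_covered_days <- function(fill_day, days_supply, stockpiling = TRUE) {
  o <- order(fill_day)
  fill_day <- fill_day[o]; days_supply <- days_supply[o]
  covered <- integer(0)
  if (stockpiling) {
    ptr <- -Inf
    for (i in seq_along(fill_day)) {
      start <- max(fill_day[i], ptr)
      covered <- c(covered, seq(start, length.out = days_supply[i]))
      ptr <- start + days_supply[i]
    }
  } else {
    for (i in seq_along(fill_day)) {
      covered <- c(covered, seq(fill_day[i], length.out = days_supply[i]))
    }
  }
  sort(unique(covered))
}

# day-by-day scanner: walk the covered-day set, split coverage segments, and
# group them into grace-period episodes
brute_episodes <- function(fill_day, days_supply, grace, fu_end,
                           stockpiling = TRUE) {
  covered <- brute_covered_days(fill_day, days_supply, stockpiling)
  seg_start <- covered[1]; last <- covered[1]
  segs <- NULL
  for (d in covered[-1]) {
    if (d > last + 1) {
      segs <- rbind(segs, c(seg_start, last + 1))
      seg_start <- d
    }
    last <- d
  }
  segs <- rbind(segs, c(seg_start, last + 1))
  # coverage starting after the end of follow-up is unobservable
  segs <- segs[segs[, 1] <= fu_end, , drop = FALSE]
  if (nrow(segs) == 0L) {
    return(data.frame(episode_index = integer(0), start_day = integer(0),
                      supply_end_day = integer(0),
                      discontinuation_day = integer(0), status = character(0),
                      reinitiation_day = integer(0)))
  }
  # group segments: gap (uncovered days between segments) > grace closes episode
  ep_start <- segs[1, 1]; ep_end <- segs[1, 2]
  eps <- NULL
  if (nrow(segs) > 1) {
    for (k in 2:nrow(segs)) {
      if (segs[k, 1] - ep_end > grace) {
        eps <- rbind(eps, c(ep_start, ep_end))
        ep_start <- segs[k, 1]
      }
      ep_end <- segs[k, 2]
    }
  }
  eps <- rbind(eps, c(ep_start, ep_end))
  data.frame(
    episode_index = seq_len(nrow(eps)),
    start_day = eps[, 1],
    supply_end_day = eps[, 2],
    discontinuation_day = ifelse(eps[, 2] + grace <= fu_end,
                                 eps[, 2] + grace, NA_integer_),
    status = ifelse(eps[, 2] + grace <= fu_end, "discontinued",
                    "ongoing_at_censor"),
    reinitiation_day = c(eps[-1, 1], NA_integer_)
  )
}

# Breslow-ties Cox partial log-likelihood for a single covariate
brute_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dead <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + sum(x[dead]) * beta - length(dead) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# random single-person fill stream for randomized oracle comparisons
random_fill_stream <- function() {
  k <- sample(1:8, 1)
  data.frame(person_id = "X",
             fill_day = sort(sample(0:1200, k)),
             days_supply = sample(1:120, k, replace = TRUE))
}

# minimal single-class cohort for hand-built fill fixtures
toy_cohort <- function(ids, index, fu_end, reason = "admin_censor") {
  data.frame(person_id = ids, drug_class = "GLP1", index_day = index,
             follow_up_end_day = fu_end, end_reason = reason,
             stringsAsFactors = FALSE)
}
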