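# Builders for small in-code fixtures.

# One assessment row; items default to zero and can be overridden by
# position, e.g. make_assessment(p = c(p3 = 3)).
make_assessment <- function(user_id = "u1", timepoint_index = 0,
                            g = integer(0), p = integer(0), b = integer(0),
                            timestamp = as.POSIXct("2022-03-01 10:00:00",
                                                   tz = "UTC")) {
  gv <- rep(0L, 7); pv <- rep(0L, 9); bv <- rep(0L, 2)
  set_items <- function(vec, vals, prefix) {
    for (nm in names(vals)) {
      vec[as.integer(sub(prefix, "", nm))] <- vals[[nm]]
    }
    if (is.null(names(vals)) && length(vals) > 0) vec <- vals
    vec
  }
  gv <- set_items(gv, g, "g"); pv <- set_items(pv, p, "p")
  bv <- set_items(bv, b, "b")
  row <- tibble::tibble(user_id = user_id,
                        timepoint_index = as.integer(timepoint_index),
                        timestamp = timestamp)
  row[paste0("g", 1:7)] <- as.list(as.integer(gv))
  row[paste0("p", 1:9)] <- as.list(as.integer(pv))
  row[c("b1", "b2")] <- as.list(as.integer(bv))
  row
}

# Random valid assessment under a running RNG stream.
random_assessment <- function(user_id = "u1") {
  make_assessment(user_id,
                  g = sample(0:3, 7, replace = TRUE),
                  p = sample(0:3, 9, replace = TRUE),
                  b = sample(0:6, 2, replace = TRUE))
}

make_event <- function(user_id, day, kind, hour = 12, timepoint_index = NA,
                       module_id = NA, start = "2022-03-01") {
  tibble::tibble(
    user_id = user_id,
    ts = as.POSIXct(start, tz = "UTC") + day * 86400 + hour * 3600,
    kind = kind,
    timepoint_index = as.integer(timepoint_index),
    module_id = as.integer(module_id)
  )
}

make_mauq <- function(user_id, ratings) {
  stopifnot(length(ratings) == 18)
  row <- tibble::tibble(user_id = user_id)
  row[paste0("m", 1:18)] <- as.list(as.integer(ratings))
  row
}
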