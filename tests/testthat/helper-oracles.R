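# Brute-force reference implementations, kept deliberately independent of the
# package internals: explicit loops, no shared helpers.

# one keypoint-stream row from x coordinates and confidences
make_frame <- function(nose_x = 120, le_x = 100, re_x = 140,
                       ear_c = c(0.9, 0.9), eye_c = c(0.9, 0.9),
                       nose_c = 0.9, timestamp = 0, person_id = 0L,
                       nose_y = 260, eye_y = 240, ear_y = 250,
                       le_ear_x = 60, re_ear_x = 180) {
  data.frame(timestamp = timestamp, person_id = person_id,
             nose_x = nose_x, nose_y = nose_y, nose_c = nose_c,
             left_eye_x = le_x, left_eye_y = eye_y, left_eye_c = eye_c[1],
             right_eye_x = re_x, right_eye_y = eye_y, right_eye_c = eye_c[2],
             left_ear_x = le_ear_x, left_ear_y = ear_y, left_ear_c = ear_c[1],
             right_ear_x = re_ear_x, right_ear_y = ear_y, right_ear_c = ear_c[2])
}

make_stream <- function(n, ...) {
  rows <- lapply(seq_len(n) - 1L, function(i) make_frame(timestamp = i / 30, ...))
  keypoint_stream(do.call(rbind, rows))
}

# brute-force gaze rule on one row
oracle_frame_gaze <- function(row, thr = 0, tol = 0.5) {
  present <- function(c) c > thr
  if (!present(row$left_ear_c) || !present(row$right_ear_c)) return(0L)
  if (!present(row$left_eye_c) || !present(row$right_eye_c) ||
      !present(row$nose_c)) return(0L)
  mid <- (row$left_eye_x + row$right_eye_x) / 2
  if (abs(row$nose_x - mid) <= tol * abs(row$left_eye_x - row$right_eye_x))
    1L else 0L
}

# brute-force majority vote onto the window grid: window w owns the 0-based
# frame indices i with floor(i / (fps*window)) == w
oracle_vote <- function(labels, fps, window_seconds) {
  fpw <- fps * window_seconds
  n <- length(labels)
  win_of <- floor((seq_len(n) - 1) / fpw)
  n_full <- floor(n / fpw)
  n_win <- n_full
  if (max(win_of) >= n_full && sum(win_of == max(win_of)) >= fpw / 2)
    n_win <- n_full + 1
  out <- integer(0)
  prev <- 0L
  for (w in seq_len(n_win) - 1) {
    idx <- which(win_of == w)
    ones <- sum(labels[idx] == 1)
    zeros <- length(idx) - ones
    if (ones > zeros) prev <- 1L else if (zeros > ones) prev <- 0L
    out <- c(out, prev)
  }
  out
}

# brute-force confusion tally
oracle_confusion <- function(truth, pred) {
  cls <- c("SG+D", "D", "SG", "Other")
  m <- matrix(0L, 4, 4, dimnames = list(truth = cls, prediction = cls))
  for (i in seq_along(truth))
    m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
  m
}

# brute-force transition scan
oracle_transitions <- function(labels) {
  recs <- NULL
  n <- length(labels)
  for (i in 2:n) {
    if (labels[i] != labels[i - 1]) {
      pre <- 1
      j <- i - 1
      while (j > 1 && labels[j - 1] == labels[j]) { pre <- pre + 1; j <- j - 1 }
      post <- 1
      j <- i
      while (j < n && labels[j + 1] == labels[j]) { post <- post + 1; j <- j + 1 }
      recs <- rbind(recs, data.frame(boundary_index = i,
                                     from_class = labels[i - 1],
                                     to_class = labels[i],
                                     pre_run = pre, post_run = post,
                                     stringsAsFactors = FALSE))
    }
  }
  recs
}

# brute-force attribution over all (error window, boundary) pairs
oracle_attribution <- function(truth, pred, radius = 2, min_run = 3) {
  recs <- oracle_transitions(truth)
  if (!is.null(recs)) recs <- recs[recs$pre_run >= min_run & recs$post_run >= min_run, ]
  count <- 0L
  for (w in seq_along(truth)) {
    if (pred[w] == truth[w]) next
    hit <- FALSE
    if (!is.null(recs) && nrow(recs)) for (j in seq_len(nrow(recs))) {
      b <- recs$boundary_index[j]
      if (abs(w - b) > radius) next
      side <- if (w < b) recs$to_class[j] else recs$from_class[j]
      if (pred[w] == side) hit <- TRUE
    }
    count <- count + as.integer(hit)
  }
  count
}

random_timeline <- function(n, seed) {
  set.seed(seed)
  # runs of random length so transitions and long runs both occur
  lab <- character(0)
  cls <- c("SG+D", "D", "SG", "Other")
  cur <- sample(cls, 1)
  while (length(lab) < n) {
    lab <- c(lab, rep(cur, sample(1:8, 1)))
    cur <- sample(setdiff(cls, cur), 1)
  }
  interaction_timeline(lab[seq_len(n)])
}
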