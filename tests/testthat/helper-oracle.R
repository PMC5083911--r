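# Independent brute-force reimplementation of the caller, used as an
# oracle on small alignments: plain loops, no shared code with the
# package internals beyond the te_alignment fields.

oracle_call <- function(aln, major = 0.85, minor = 1 - major) {
  rows <- strsplit(aln$residues, "", fixed = TRUE)
  n_copies <- length(rows)
  n_cols <- length(rows[[1]])

  anc <- character(n_cols)      # called ancestral allele or NA
  freq <- vector("list", n_cols)
  for (j in seq_len(n_cols)) {
    chars <- vapply(rows, `[[`, character(1), j)
    chars <- chars[chars != "N"]
    tab <- table(factor(chars, levels = c("A", "C", "G", "T", "-")))
    f <- as.numeric(tab) / max(sum(tab), 1)
    names(f) <- names(tab)
    freq[[j]] <- f
    best <- names(f)[which.max(f)]
    anc[j] <- if (length(chars) > 0 && max(f) >= major) best else NA
  }
  is_ins <- !is.na(anc) & anc == "-"
  # ancestral positions over non-insertion columns (ambiguous columns
  # consume a position unless gaps outnumber bases)
  consumes <- logical(n_cols)
  for (j in seq_len(n_cols)) {
    f <- freq[[j]]
    consumes[j] <- if (!is.na(anc[j])) anc[j] != "-" else f[["-"]] <= sum(f[c("A", "C", "G", "T")])
  }
  pos_of <- cumsum(consumes)
  pos_of[!consumes] <- NA

  events <- list()
  add <- function(kind, s, e, a, d, len, cid) {
    events[[length(events) + 1]] <<- data.frame(
      event_kind = kind, interval_start = s, interval_end = e,
      anc_alleles = a, der_alleles = d, length = len, copy_id = cid,
      stringsAsFactors = FALSE)
  }
  anc_cols <- which(consumes)
  for (i in seq_len(n_copies)) {
    cid <- aln$copy_id[i]
    ## substitution runs over consecutive ancestral positions
    run_a <- run_d <- character(0); run_start <- NA
    flush <- function() {
      if (length(run_a) > 0) {
        add("substitution", run_start, run_start + length(run_a) - 1L,
            paste(run_a, collapse = ""), paste(run_d, collapse = ""),
            length(run_a), cid)
      }
      run_a <<- character(0); run_d <<- character(0); run_start <<- NA
    }
    for (j in anc_cols) {
      ch <- rows[[i]][j]
      hit <- !is.na(anc[j]) && anc[j] != "-" && ch %in% c("A", "C", "G", "T") &&
        ch != anc[j] && freq[[j]][[ch]] <= minor
      if (hit) {
        if (length(run_a) == 0) run_start <- pos_of[j]
        run_a <- c(run_a, anc[j]); run_d <- c(run_d, ch)
      } else flush()
    }
    flush()
    ## deletion runs
    run_a <- character(0); run_start <- NA
    dflush <- function() {
      if (length(run_a) > 0) {
        add("deletion", run_start - 1L, run_start + length(run_a),
            paste(run_a, collapse = ""), "", length(run_a), cid)
      }
      run_a <<- character(0); run_start <<- NA
    }
    for (j in anc_cols) {
      ch <- rows[[i]][j]
      hit <- !is.na(anc[j]) && anc[j] != "-" && ch == "-" &&
        freq[[j]][["-"]] <= minor
      if (hit) {
        if (length(run_a) == 0) run_start <- pos_of[j]
        run_a <- c(run_a, anc[j])
      } else dflush()
    }
    dflush()
    ## insertion runs inside insertion-column stretches
    j <- 1
    while (j <= n_cols) {
      if (is_ins[j] && rows[[i]][j] %in% c("A", "C", "G", "T")) {
        k <- j
        while (k + 1 <= n_cols && is_ins[k + 1] &&
               rows[[i]][k + 1] %in% c("A", "C", "G", "T")) k <- k + 1
        left <- if (j == 1) 0L else max(c(0, pos_of[seq_len(j - 1)]), na.rm = TRUE)
        add("insertion", as.integer(left), as.integer(left) + 1L, "",
            paste(rows[[i]][j:k], collapse = ""), k - j + 1L, cid)
        j <- k + 1
      } else j <- j + 1
    }
  }
  if (length(events) == 0) {
    return(data.frame(event_kind = character(), interval_start = integer(),
                      interval_end = integer(), anc_alleles = character(),
                      der_alleles = character(), length = integer(),
                      copy_ids = character(), stringsAsFactors = FALSE))
  }
  ev <- do.call(rbind, events)
  key <- paste(ev$event_kind, ev$interval_start, ev$interval_end,
               ev$anc_alleles, ev$der_alleles)
  out <- lapply(split(ev, key), function(d) {
    d$copy_ids <- paste(sort(unique(d$copy_id)), collapse = ",")
    d[1, c("event_kind", "interval_start", "interval_end", "anc_alleles",
           "der_alleles", "length", "copy_ids")]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$interval_start, out$event_kind, out$der_alleles), ]
}

event_key <- function(ev, carriers = TRUE) {
  k <- paste(ev$event_kind, ev$interval_start, ev$interval_end,
             ev$anc_alleles, ev$der_alleles)
  if (carriers && "copy_ids" %in% names(ev)) k <- paste(k, ev$copy_ids)
  sort(k)
}

# random small gapped alignment: ancestral plus sparse substitutions,
# short deletions, and occasional minority-insertion columns
random_alignment <- function(n_copies = 8, n_anc = 40, p_sub = 0.03,
                             p_del = 0.01, p_ins_col = 0.05) {
  anc <- sample(c("A", "C", "G", "T"), n_anc, replace = TRUE)
  rows <- replicate(n_copies, anc, simplify = FALSE)
  for (i in seq_len(n_copies)) {
    for (j in seq_len(n_anc)) {
      r <- stats::runif(1)
      if (r < p_sub) {
        rows[[i]][j] <- sample(setdiff(c("A", "C", "G", "T"), anc[j]), 1)
      } else if (r < p_sub + p_del) {
        L <- sample(1:3, 1)
        rows[[i]][j:min(n_anc, j + L - 1)] <- "-"
      }
    }
  }
  # minority insertion columns
  n_ins <- stats::rbinom(1, 3, p_ins_col * 4)
  m <- do.call(rbind, rows)
  for (q in seq_len(n_ins)) {
    at <- sample(ncol(m) + 1, 1)
    col <- rep("-", n_copies)
    col[sample(n_copies, 1)] <- sample(c("A", "C", "G", "T"), 1)
    m <- cbind(m[, seq_len(at - 1), drop = FALSE], col,
               m[, seq(at, length.out = ncol(m) - at + 1), drop = FALSE])
  }
  te_alignment(tibble::tibble(
    copy_id = sprintf("c%02d", seq_len(n_copies)),
    population = "P1",
    residues = apply(m, 1, paste, collapse = "")
  ))
}
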