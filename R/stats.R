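#' Shapiro-Wilk normality test
#'
#' Validating wrapper around the standard Royston algorithm
#' (\code{stats::shapiro.test}): requires 3 <= n <= 5000 and nonzero
#' variance.
#'
#' @param values numeric sample.
#' @return An object of class \code{htest} (statistic W, p-value).
#' @export
shapiroWilk <- function(values) {
    values <- as.numeric(values)
    values <- values[is.finite(values)]
    n <- length(values)
    if (n < 3 || n > 5000)
        stop("Shapiro-Wilk requires 3 <= n <= 5000")
    if (stats::var(values) == 0)
        stop("Shapiro-Wilk requires a sample with nonzero variance")
    stats::shapiro.test(values)
}

#' Paired two-sided t test
#'
#' t = mean(d) / (sd(d)/sqrt(n)) on the differences d = x - y, with
#' df = n - 1 and a two-sided p value. Zero-variance differences have the
#' conventional limits: all-zero differences give t = 0, p = 1; a nonzero
#' constant difference gives t = +/-Inf, p = 0.
#'
#' @param x,y paired measurements of equal length >= 2 (common unit).
#' @return An object of class \code{htest} with statistic, df (parameter)
#'   and p-value. Cross-checked against \code{stats::t.test(paired=TRUE)}
#'   for non-degenerate input.
#' @examples
#' pairedT(c(2, 3, 4), c(1, 1, 1))  # t = 2*sqrt(3), df = 2
#' @export
pairedT <- function(x, y) {
    x <- as.numeric(x); y <- as.numeric(y)
    if (length(x) != length(y))
        stop("x and y must be paired samples of equal length")
    if (anyNA(x) || anyNA(y))
        stop("missing pairs are not allowed; exclude subjects listwise")
    n <- length(x)
    if (n < 2) stop("paired t requires n >= 2")
    d <- x - y
    sdd <- stats::sd(d)
    m <- mean(d)
    if (sdd == 0) {
        tval <- if (m == 0) 0 else sign(m) * Inf
        p <- if (m == 0) 1 else 0
    } else {
        tval <- m / (sdd / sqrt(n))
        p <- 2 * stats::pt(-abs(tval), df = n - 1)
    }
    structure(list(statistic = c(t = tval), parameter = c(df = n - 1),
                   p.value = p, estimate = c(`mean difference` = m),
                   alternative = "two.sided",
                   method = "Paired t-test",
                   data.name = "x - y"),
              class = "htest")
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA (equal-variance F test) across k
#' groups: F with (k - 1, N - k) degrees of freedom.
#'
#' @param groups list of numeric vectors, >= 2 groups with n >= 2 each.
#' @return An object of class \code{htest} (F statistic, num/denom df,
#'   p-value).
#' @export
anovaOneway <- function(groups) {
    if (!is.list(groups) || length(groups) < 2)
        stop("need at least two groups")
    if (any(vapply(groups, length, 0L) < 2))
        stop("each group needs at least two observations")
    values <- unlist(groups, use.names = FALSE)
    if (stats::var(values) == 0)
        stop("degenerate input: all observations identical")
    g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
    stats::oneway.test(values ~ g, var.equal = TRUE)
}

## two-way crossed mean squares (subjects x raters, one observation/cell)
.twoWayMS <- function(m) {
    n <- nrow(m); k <- ncol(m)
    grand <- mean(m)
    SSR <- k * sum((rowMeans(m) - grand)^2)
    SSC <- n * sum((colMeans(m) - grand)^2)
    SST <- sum((m - grand)^2)
    SSE <- SST - SSR - SSC
    list(MSR = SSR / (n - 1), MSC = SSC / (k - 1),
         MSE = SSE / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Intraclass correlation, two-way model, absolute agreement
#'
#' Single-measure ICC(A,1) (default) or average-measure ICC(A,k) from the
#' two-way crossed mean squares of a complete subjects x raters table:
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}.}
#' Absolute agreement penalizes systematic rater offsets (unlike
#' consistency-type ICC). The confidence interval follows the standard
#' F-distribution approximation with Satterthwaite degrees of freedom.
#'
#' @param table complete numeric matrix, subjects in rows (n >= 2), raters
#'   in columns (k >= 2), one measurement per cell.
#' @param type "single" (ICC(A,1), the conservative default for one rating
#'   per cell) or "average" (ICC(A,k)).
#' @param conf confidence level.
#' @return A list with \code{icc}, \code{lower}, \code{upper}, \code{type}
#'   and the mean squares.
#' @examples
#' m <- cbind(c(9, 7, 5, 3), c(9.1, 7.2, 4.9, 3.1))
#' iccAbsoluteAgreement(m)$icc
#' @export
iccAbsoluteAgreement <- function(table, type = c("single", "average"),
                                 conf = 0.95) {
    type <- match.arg(type)
    m <- as.matrix(table)
    if (anyNA(m)) stop("the rater table must be complete (no missing cells)")
    if (nrow(m) < 2 || ncol(m) < 2)
        stop("need at least 2 subjects and 2 raters")
    ms <- .twoWayMS(m)
    n <- ms$n; k <- ms$k
    num <- ms$MSR - ms$MSE
    if (type == "single") {
        den <- ms$MSR + (k - 1) * ms$MSE + k / n * (ms$MSC - ms$MSE)
    } else {
        den <- ms$MSR + (ms$MSC - ms$MSE) / n
    }
    icc <- if (den == 0) 1 else num / den
    ## McGraw & Wong F-based interval for ICC(A,1)/(A,k)
    lower <- upper <- NA_real_
    if (ms$MSE > 0 && icc < 1) {
        alpha <- 1 - conf
        a <- k * icc / (n * (1 - icc))
        b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
        v <- (a * ms$MSC + b * ms$MSE)^2 /
            ((a * ms$MSC)^2 / (k - 1) +
             (b * ms$MSE)^2 / ((n - 1) * (k - 1)))
        FL <- stats::qf(1 - alpha / 2, n - 1, v)
        FU <- stats::qf(1 - alpha / 2, v, n - 1)
        lower <- n * (ms$MSR - FL * ms$MSE) /
            (FL * (k * ms$MSC + (k * n - k - n) * ms$MSE) + n * ms$MSR)
        upper <- n * (FU * ms$MSR - ms$MSE) /
            (k * ms$MSC + (k * n - k - n) * ms$MSE + n * FU * ms$MSR)
        if (type == "average") {
            ## step-up of the single-measure bounds (Spearman-Brown form
            ## used by the standard two-way absolute-agreement interval)
            lower <- lower * k / (1 + (k - 1) * lower)
            upper <- upper * k / (1 + (k - 1) * upper)
        }
    } else if (icc >= 1) {
        lower <- upper <- 1
    }
    list(icc = icc, lower = lower, upper = upper, type = type, conf = conf,
         MSR = ms$MSR, MSC = ms$MSC, MSE = ms$MSE, n = n, k = k)
}

#' Build the volume comparison report
#'
#' Reproduces the study-style analysis over a long-format volume table with
#' columns \code{subject}, \code{method} (e.g. MD / MKT / histology),
#' \code{volume_cm3} and optional \code{rater} and \code{repeat}
#' (re-measurement) columns. Subjects missing any method are excluded
#' listwise with a warning. The report contains per-method means +/- SD,
#' Shapiro-Wilk normality checks, two-sided paired t tests for every method
#' pair, the MKT-over-MD mismatch percent of the group means, and
#' absolute-agreement ICC tables per method when repeated ratings exist.
#'
#' @param volumes data.frame as described above (primary ratings are
#'   rater/repeat number 1 when those columns are present).
#' @param alpha significance level annotated in the tests table.
#' @return A list of class \code{fkReport} with elements \code{summary},
#'   \code{normality}, \code{tests} (data.frames), \code{mismatchPercent},
#'   \code{icc} (list or NULL), \code{excluded} (subjects dropped).
#' @export
buildReport <- function(volumes, alpha = 0.05) {
    need <- c("subject", "method", "volume_cm3")
    if (!all(need %in% names(volumes)))
        stop("volumes must contain columns subject, method, volume_cm3")
    volumes$subject <- as.character(volumes$subject)
    volumes$method <- as.character(volumes$method)
    hasRater <- "rater" %in% names(volumes)
    hasRepeat <- "repeat" %in% names(volumes)
    primary <- volumes
    if (hasRater)
        primary <- primary[primary$rater == sort(unique(primary$rater))[1],
                           , drop = FALSE]
    if (hasRepeat)
        primary <- primary[primary[["repeat"]] ==
                           sort(unique(primary[["repeat"]]))[1], ,
                           drop = FALSE]
    methods <- sort(unique(primary$method))
    ## listwise exclusion of subjects without a complete method set
    bySubject <- split(primary$method, primary$subject)
    complete <- names(bySubject)[vapply(bySubject, function(m)
        all(methods %in% m), TRUE)]
    excluded <- setdiff(unique(primary$subject), complete)
    if (length(excluded))
        warning("excluding subjects without complete data: ",
                paste(excluded, collapse = ", "))
    primary <- primary[primary$subject %in% complete, , drop = FALSE]
    if (!length(complete)) stop("no subjects with complete data")
    wide <- do.call(cbind, lapply(methods, function(m) {
        v <- primary[primary$method == m, ]
        stats::setNames(v$volume_cm3[match(complete, v$subject)], complete)
    }))
    colnames(wide) <- methods
    summary <- data.frame(method = methods,
                          n = nrow(wide),
                          mean_cm3 = colMeans(wide),
                          sd_cm3 = apply(wide, 2, stats::sd),
                          row.names = NULL)
    normality <- do.call(rbind, lapply(methods, function(m) {
        res <- tryCatch(shapiroWilk(wide[, m]), error = function(e) NULL)
        data.frame(method = m,
                   W = if (is.null(res)) NA else unname(res$statistic),
                   p = if (is.null(res)) NA else res$p.value)
    }))
    pairs <- if (length(methods) >= 2)
        utils::combn(methods, 2, simplify = FALSE) else list()
    tests <- do.call(rbind, lapply(pairs, function(p) {
        res <- pairedT(wide[, p[1]], wide[, p[2]])
        data.frame(method1 = p[1], method2 = p[2],
                   t = unname(res$statistic), df = unname(res$parameter),
                   p = res$p.value,
                   significant = res$p.value <= alpha)
    }))
    mm <- NA_real_
    if (all(c("MD", "MKT") %in% methods))
        mm <- mismatchPercent(mean(wide[, "MKT"]), mean(wide[, "MD"]))
    icc <- NULL
    if (hasRater || hasRepeat) {
        colid <- if (hasRater && hasRepeat)
            paste(volumes$rater, volumes[["repeat"]], sep = ".")
        else if (hasRater) as.character(volumes$rater)
        else as.character(volumes[["repeat"]])
        icc <- lapply(stats::setNames(methods, methods), function(m) {
            v <- volumes[volumes$method == m & volumes$subject %in%
                         complete, , drop = FALSE]
            cid <- colid[volumes$method == m & volumes$subject %in% complete]
            tab <- tapply(v$volume_cm3, list(v$subject, cid), mean)
            if (is.null(dim(tab)) || ncol(tab) < 2 || anyNA(tab))
                return(NULL)
            iccAbsoluteAgreement(tab)
        })
        icc <- icc[!vapply(icc, is.null, TRUE)]
        if (!length(icc)) icc <- NULL
    }
    structure(list(summary = summary, normality = normality, tests = tests,
                   mismatchPercent = mm, icc = icc, excluded = excluded,
                   alpha = alpha, subjects = complete),
              class = "fkReport")
}

#' @export
print.fkReport <- function(x, ...) {
    cat("Volume report over", length(x$subjects), "subjects")
    if (length(x$excluded))
        cat(" (excluded:", paste(x$excluded, collapse = ", "), ")")
    cat("\n\nGroup means +/- SD (cm^3):\n")
    print(x$summary, row.names = FALSE)
    if (!is.null(x$tests)) {
        cat("\nPaired two-sided t tests (alpha =", x$alpha, "):\n")
        print(x$tests, row.names = FALSE)
    }
    if (!is.na(x$mismatchPercent))
        cat(sprintf("\nMKT-over-MD volume mismatch: %.1f%%\n",
                    x$mismatchPercent))
    if (!is.null(x$icc)) {
        cat("\nAbsolute-agreement ICC (single measure):\n")
        for (m in names(x$icc))
            cat(sprintf("  %s: ICC = %.4f [%.4f, %.4f]\n", m,
                        x$icc[[m]]$icc, x$icc[[m]]$lower, x$icc[[m]]$upper))
    }
    invisible(x)
}

#' Write a volume report to CSV and JSON
#'
#' Writes \code{summary.csv}, \code{tests.csv} and \code{report.json} into
#' a directory.
#'
#' @param report an object from [buildReport()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeReport <- function(report, dir) {
    stopifnot(inherits(report, "fkReport"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p1 <- file.path(dir, "summary.csv")
    p2 <- file.path(dir, "tests.csv")
    p3 <- file.path(dir, "report.json")
    utils::write.csv(report$summary, p1, row.names = FALSE)
    tests <- report$tests
    if (is.null(tests))
        tests <- data.frame(method1 = character(0), method2 = character(0),
                            t = numeric(0), df = numeric(0), p = numeric(0),
                            significant = logical(0))
    utils::write.csv(tests, p2, row.names = FALSE)
    json <- list(summary = report$summary, normality = report$normality,
                 tests = report$tests,
                 mismatch_percent = report$mismatchPercent,
                 excluded = report$excluded)
    if (!is.null(report$icc))
        json$icc <- lapply(report$icc, function(r)
            r[c("icc", "lower", "upper", "type")])
    jsonlite::write_json(json, p3, auto_unbox = TRUE, digits = NA,
                         na = "null")
    invisible(c(p1, p2, p3))
}
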