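# Independent brute-force oracle for the balanced 2x2x2 mixed design:
# classical cell/marginal-mean sums of squares, no aov machinery.
anova_oracle <- function(frame) {
  y <- frame$value
  g <- as.character(frame$group); h <- as.character(frame$hemisphere)
  r <- as.character(frame$region); s <- as.character(frame$subject_id)
  n <- length(unique(s)) / length(unique(g))  # subjects per group
  gm <- mean(y)
  m_g <- tapply(y, g, mean); m_h <- tapply(y, h, mean)
  m_r <- tapply(y, r, mean)
  m_gh <- tapply(y, list(g, h), mean); m_gr <- tapply(y, list(g, r), mean)
  m_hr <- tapply(y, list(h, r), mean)
  m_ghr <- tapply(y, list(g, h, r), mean)
  m_s <- tapply(y, s, mean)
  m_sh <- tapply(y, list(s, h), mean); m_sr <- tapply(y, list(s, r), mean)
  g_of_s <- tapply(g, s, `[`, 1)
  ss_g <- 4 * n * sum((m_g - gm)^2)
  ss_subj <- 4 * sum((m_s - gm)^2)
  ss_s_in_g <- ss_subj - ss_g
  ss_h <- 4 * n * sum((m_h - gm)^2)
  dc2 <- function(m, ma, mb) sweep(sweep(m, 1, ma - gm), 2, mb - gm) - gm
  ss_gh <- 2 * n * sum((dc2(m_gh, m_g, m_h))^2)
  ss_r <- 4 * n * sum((m_r - gm)^2)
  ss_gr <- 2 * n * sum((dc2(m_gr, m_g, m_r))^2)
  ss_hr <- 2 * n * sum((dc2(m_hr, m_h, m_r))^2)
  # subject x hemisphere within groups (error stratum for H, GxH)
  dev_sh <- m_sh
  for (si in rownames(m_sh))
    dev_sh[si, ] <- m_sh[si, ] - m_s[si] - (m_gh[g_of_s[si], ] -
                                              m_g[g_of_s[si]])
  ss_h_s <- 2 * sum(dev_sh^2)
  dev_sr <- m_sr
  for (si in rownames(m_sr))
    dev_sr[si, ] <- m_sr[si, ] - m_s[si] - (m_gr[g_of_s[si], ] -
                                              m_g[g_of_s[si]])
  ss_r_s <- 2 * sum(dev_sr^2)
  # three-way interaction via triple centering
  ss_ghr <- 0
  for (gi in names(m_g)) for (hi in names(m_h)) for (ri in names(m_r)) {
    dev <- m_ghr[gi, hi, ri] - m_gh[gi, hi] - m_gr[gi, ri] -
      m_hr[hi, ri] + m_g[gi] + m_h[hi] + m_r[ri] - gm
    ss_ghr <- ss_ghr + n * dev^2
  }
  ss_tot <- sum((y - gm)^2)
  ss_hr_s <- ss_tot - ss_g - ss_s_in_g - ss_h - ss_gh - ss_h_s -
    ss_r - ss_gr - ss_r_s - ss_hr - ss_ghr
  dfe_b <- 2 * (n - 1)
  list(
    group = c(ss_g / (ss_s_in_g / dfe_b), 1, dfe_b),
    hemisphere = c(ss_h / (ss_h_s / dfe_b), 1, dfe_b),
    `group x hemisphere` = c(ss_gh / (ss_h_s / dfe_b), 1, dfe_b),
    region = c(ss_r / (ss_r_s / dfe_b), 1, dfe_b),
    `group x region` = c(ss_gr / (ss_r_s / dfe_b), 1, dfe_b),
    `hemisphere x region` = c(ss_hr / (ss_hr_s / dfe_b), 1, dfe_b),
    `group x hemisphere x region` = c(ss_ghr / (ss_hr_s / dfe_b), 1, dfe_b)
  )
}

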