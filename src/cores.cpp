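// Recurrent cores for stateful encoders: forward passes, full backpropagation
// through time (BPTT), truncated BPTT with and without warmup, and single-step
// updates. All cores map an input sequence U (In x T) to an output state
// sequence (G x T) consumed by a linear readout on the R side.
//
// Gradient conventions: d_states is dLoss/d(output states); backward routines
// return dLoss/d(parameters) and dLoss/dU. The initial hidden state is the
// constant zero vector, so no gradient is returned for it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::as;
using Rcpp::stop;

static inline vec sigmoid_vec(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

// ---------------------------------------------------------------------------
// Elman core: h_t = tanh(W u_t + U h_{t-1} + b)
// ---------------------------------------------------------------------------

struct ElmanParams {
  mat W, U; vec b;
  explicit ElmanParams(const List& p)
    : W(as<mat>(p["W"])), U(as<mat>(p["U"])), b(as<vec>(p["b"])) {}
};

struct ElmanGrads {
  mat W, U; vec b;
  explicit ElmanGrads(const ElmanParams& p)
    : W(size(p.W), fill::zeros), U(size(p.U), fill::zeros),
      b(size(p.b), fill::zeros) {}
  List toList() const {
    return List::create(Named("W") = W, Named("U") = U, Named("b") = b);
  }
};

static vec elman_step(const ElmanParams& p, const vec& u, const vec& h_prev) {
  return tanh(p.W * u + p.U * h_prev + p.b);
}

// One-step backward. d_h: gradient arriving at h_t. Returns d_h_prev,
// accumulates parameter grads and d_u.
static vec elman_step_bwd(const ElmanParams& p, ElmanGrads& g,
                          const vec& u, const vec& h_prev, const vec& h_t,
                          const vec& d_h, vec& d_u) {
  vec dpre = d_h % (1.0 - h_t % h_t);
  g.W += dpre * u.t();
  g.U += dpre * h_prev.t();
  g.b += dpre;
  d_u += p.W.t() * dpre;
  return p.U.t() * dpre;
}

// ---------------------------------------------------------------------------
// GRU core (PyTorch convention):
//   z = sigm(Wz u + bwz + Uz h + buz)
//   r = sigm(Wr u + bwr + Ur h + bur)
//   n = tanh(Wn u + bwn + r  % (Un h + bun))
//   h' = (1 - z) % n + z % h
// ---------------------------------------------------------------------------

struct GruParams {
  mat Wz, Wr, Wn, Uz, Ur, Un; vec bwz, bwr, bwn, buz, bur, bun;
  explicit GruParams(const List& p)
    : Wz(as<mat>(p["Wz"])), Wr(as<mat>(p["Wr"])), Wn(as<mat>(p["Wn"])),
      Uz(as<mat>(p["Uz"])), Ur(as<mat>(p["Ur"])), Un(as<mat>(p["Un"])),
      bwz(as<vec>(p["bwz"])), bwr(as<vec>(p["bwr"])), bwn(as<vec>(p["bwn"])),
      buz(as<vec>(p["buz"])), bur(as<vec>(p["bur"])), bun(as<vec>(p["bun"])) {}
};

struct GruGrads {
  mat Wz, Wr, Wn, Uz, Ur, Un; vec bwz, bwr, bwn, buz, bur, bun;
  explicit GruGrads(const GruParams& p)
    : Wz(size(p.Wz), fill::zeros), Wr(size(p.Wr), fill::zeros),
      Wn(size(p.Wn), fill::zeros), Uz(size(p.Uz), fill::zeros),
      Ur(size(p.Ur), fill::zeros), Un(size(p.Un), fill::zeros),
      bwz(size(p.bwz), fill::zeros), bwr(size(p.bwr), fill::zeros),
      bwn(size(p.bwn), fill::zeros), buz(size(p.buz), fill::zeros),
      bur(size(p.bur), fill::zeros), bun(size(p.bun), fill::zeros) {}
  List toList() const {
    return List::create(Named("Wz") = Wz, Named("Wr") = Wr, Named("Wn") = Wn,
                        Named("Uz") = Uz, Named("Ur") = Ur, Named("Un") = Un,
                        Named("bwz") = bwz, Named("bwr") = bwr,
                        Named("bwn") = bwn, Named("buz") = buz,
                        Named("bur") = bur, Named("bun") = bun);
  }
};

struct GruStepCache { vec z, r, n, A; };

static vec gru_step(const GruParams& p, const vec& u, const vec& h_prev,
                    GruStepCache& c) {
  c.z = sigmoid_vec(p.Wz * u + p.bwz + p.Uz * h_prev + p.buz);
  c.r = sigmoid_vec(p.Wr * u + p.bwr + p.Ur * h_prev + p.bur);
  c.A = p.Un * h_prev + p.bun;
  c.n = tanh(p.Wn * u + p.bwn + c.r % c.A);
  return (1.0 - c.z) % c.n + c.z % h_prev;
}

static vec gru_step_bwd(const GruParams& p, GruGrads& g, const vec& u,
                        const vec& h_prev, const GruStepCache& c,
                        const vec& d_h, vec& d_u) {
  vec dn = d_h % (1.0 - c.z);
  vec dz = d_h % (h_prev - c.n);
  vec d_h_prev = d_h % c.z;
  vec dn_pre = dn % (1.0 - c.n % c.n);
  g.Wn += dn_pre * u.t();
  g.bwn += dn_pre;
  vec dr = dn_pre % c.A;
  vec dA = dn_pre % c.r;
  g.Un += dA * h_prev.t();
  g.bun += dA;
  d_h_prev += p.Un.t() * dA;
  vec dz_pre = dz % c.z % (1.0 - c.z);
  vec dr_pre = dr % c.r % (1.0 - c.r);
  g.Wz += dz_pre * u.t(); g.Uz += dz_pre * h_prev.t();
  g.bwz += dz_pre; g.buz += dz_pre;
  g.Wr += dr_pre * u.t(); g.Ur += dr_pre * h_prev.t();
  g.bwr += dr_pre; g.bur += dr_pre;
  d_h_prev += p.Uz.t() * dz_pre + p.Ur.t() * dr_pre;
  d_u += p.Wz.t() * dz_pre + p.Wr.t() * dr_pre + p.Wn.t() * dn_pre;
  return d_h_prev;
}

// ---------------------------------------------------------------------------
// LSTM core (single bias set):
//   i,f,o = sigm(W. u + U. h + b.), g = tanh(Wg u + Ug h + bg)
//   c' = f % c + i % g ; h' = o % tanh(c')
// ---------------------------------------------------------------------------

struct LstmParams {
  mat Wi, Wf, Wg, Wo, Ui, Uf, Ug, Uo; vec bi, bf, bg, bo;
  explicit LstmParams(const List& p)
    : Wi(as<mat>(p["Wi"])), Wf(as<mat>(p["Wf"])), Wg(as<mat>(p["Wg"])),
      Wo(as<mat>(p["Wo"])), Ui(as<mat>(p["Ui"])), Uf(as<mat>(p["Uf"])),
      Ug(as<mat>(p["Ug"])), Uo(as<mat>(p["Uo"])),
      bi(as<vec>(p["bi"])), bf(as<vec>(p["bf"])), bg(as<vec>(p["bg"])),
      bo(as<vec>(p["bo"])) {}
};

struct LstmGrads {
  mat Wi, Wf, Wg, Wo, Ui, Uf, Ug, Uo; vec bi, bf, bg, bo;
  explicit LstmGrads(const LstmParams& p)
    : Wi(size(p.Wi), fill::zeros), Wf(size(p.Wf), fill::zeros),
      Wg(size(p.Wg), fill::zeros), Wo(size(p.Wo), fill::zeros),
      Ui(size(p.Ui), fill::zeros), Uf(size(p.Uf), fill::zeros),
      Ug(size(p.Ug), fill::zeros), Uo(size(p.Uo), fill::zeros),
      bi(size(p.bi), fill::zeros), bf(size(p.bf), fill::zeros),
      bg(size(p.bg), fill::zeros), bo(size(p.bo), fill::zeros) {}
  List toList() const {
    return List::create(Named("Wi") = Wi, Named("Wf") = Wf, Named("Wg") = Wg,
                        Named("Wo") = Wo, Named("Ui") = Ui, Named("Uf") = Uf,
                        Named("Ug") = Ug, Named("Uo") = Uo,
                        Named("bi") = bi, Named("bf") = bf, Named("bg") = bg,
                        Named("bo") = bo);
  }
};

struct LstmStepCache { vec i, f, g, o, c; };

static vec lstm_step(const LstmParams& p, const vec& u, const vec& h_prev,
                     const vec& c_prev, LstmStepCache& s) {
  s.i = sigmoid_vec(p.Wi * u + p.Ui * h_prev + p.bi);
  s.f = sigmoid_vec(p.Wf * u + p.Uf * h_prev + p.bf);
  s.g = tanh(p.Wg * u + p.Ug * h_prev + p.bg);
  s.o = sigmoid_vec(p.Wo * u + p.Uo * h_prev + p.bo);
  s.c = s.f % c_prev + s.i % s.g;
  return s.o % tanh(s.c);
}

// d_h, d_c: incoming grads at h_t, c_t. Returns d_h_prev; d_c updated in
// place to d_c_prev.
static vec lstm_step_bwd(const LstmParams& p, LstmGrads& g, const vec& u,
                         const vec& h_prev, const vec& c_prev,
                         const LstmStepCache& s, const vec& d_h, vec& d_c,
                         vec& d_u) {
  vec tc = tanh(s.c);
  vec do_ = d_h % tc;
  d_c += d_h % s.o % (1.0 - tc % tc);
  vec di = d_c % s.g;
  vec dg = d_c % s.i;
  vec df = d_c % c_prev;
  vec d_c_prev = d_c % s.f;
  vec di_pre = di % s.i % (1.0 - s.i);
  vec df_pre = df % s.f % (1.0 - s.f);
  vec dg_pre = dg % (1.0 - s.g % s.g);
  vec do_pre = do_ % s.o % (1.0 - s.o);
  g.Wi += di_pre * u.t(); g.Ui += di_pre * h_prev.t(); g.bi += di_pre;
  g.Wf += df_pre * u.t(); g.Uf += df_pre * h_prev.t(); g.bf += df_pre;
  g.Wg += dg_pre * u.t(); g.Ug += dg_pre * h_prev.t(); g.bg += dg_pre;
  g.Wo += do_pre * u.t(); g.Uo += do_pre * h_prev.t(); g.bo += do_pre;
  vec d_h_prev = p.Ui.t() * di_pre + p.Uf.t() * df_pre +
                 p.Ug.t() * dg_pre + p.Uo.t() * do_pre;
  d_u += p.Wi.t() * di_pre + p.Wf.t() * df_pre +
         p.Wg.t() * dg_pre + p.Wo.t() * do_pre;
  d_c = d_c_prev;
  return d_h_prev;
}

// ---------------------------------------------------------------------------
// Diagonal state-space core with zero-order-hold discretisation:
//   lambda = -exp(a_log), Delta = exp(logdt)
//   Abar = exp(Delta % lambda), coef = (Abar - 1) / lambda
//   s_t = Abar % s_{t-1} + coef % (B u_t)
//   y_t = C s_t + D u_t
// The output sequence is y; the carried state is s.
// ---------------------------------------------------------------------------

struct SsmParams {
  vec a_log, logdt; mat B, C, D;
  vec lambda, Delta, Abar, coef;  // derived
  explicit SsmParams(const List& p)
    : a_log(as<vec>(p["a_log"])), logdt(as<vec>(p["logdt"])),
      B(as<mat>(p["B"])), C(as<mat>(p["C"])), D(as<mat>(p["D"])) {
    lambda = -exp(a_log);
    Delta = exp(logdt);
    Abar = exp(Delta % lambda);
    coef = (Abar - 1.0) / lambda;
  }
};

struct SsmGrads {
  vec a_log, logdt; mat B, C, D;
  vec dAbar, dcoef;  // accumulated wrt derived quantities
  explicit SsmGrads(const SsmParams& p)
    : a_log(size(p.a_log), fill::zeros), logdt(size(p.logdt), fill::zeros),
      B(size(p.B), fill::zeros), C(size(p.C), fill::zeros),
      D(size(p.D), fill::zeros),
      dAbar(size(p.Abar), fill::zeros), dcoef(size(p.coef), fill::zeros) {}
  void finalize(const SsmParams& p) {
    vec d_lambda = dAbar % (p.Delta % p.Abar) +
      dcoef % ((p.Delta % p.Abar % p.lambda - (p.Abar - 1.0)) /
               (p.lambda % p.lambda));
    vec d_Delta = dAbar % (p.lambda % p.Abar) + dcoef % p.Abar;
    a_log = d_lambda % p.lambda;  // d lambda / d a_log = lambda
    logdt = d_Delta % p.Delta;
  }
  List toList() const {
    return List::create(Named("a_log") = a_log, Named("logdt") = logdt,
                        Named("B") = B, Named("C") = C, Named("D") = D);
  }
};

static vec ssm_step(const SsmParams& p, const vec& u, const vec& s_prev,
                    vec& s_out) {
  s_out = p.Abar % s_prev + p.coef % (p.B * u);
  return p.C * s_out + p.D * u;
}

// Backward through the recurrence only (the C/D output map is handled by the
// caller): given d_s at s_t, returns d_s_prev, accumulates grads and d_u.
static vec ssm_rec_bwd(const SsmParams& p, SsmGrads& g, const vec& u,
                       const vec& s_prev, const vec& d_s, vec& d_u) {
  vec pvec = p.B * u;
  g.dAbar += d_s % s_prev;
  g.dcoef += d_s % pvec;
  vec d_p = d_s % p.coef;
  g.B += d_p * u.t();
  d_u += p.B.t() * d_p;
  return p.Abar % d_s;
}

// ===========================================================================
// Drivers
// ===========================================================================

// Full forward over a sequence. Returns the output states, the per-step
// cache needed by the backward passes, and the final carried state.
// [[Rcpp::export]]
List core_forward_cpp(std::string type, List params, const arma::mat& U,
                      Rcpp::Nullable<Rcpp::List> state0 = R_NilValue) {
  const uword T = U.n_cols;
  if (type == "elman") {
    ElmanParams p(params);
    const uword G = p.b.n_elem;
    vec h(G, fill::zeros);
    if (state0.isNotNull()) h = as<vec>(List(state0)["h"]);
    vec h0 = h;
    mat H(G, T);
    for (uword t = 0; t < T; ++t) { h = elman_step(p, U.col(t), h); H.col(t) = h; }
    return List::create(Named("states") = H, Named("h0") = h0,
                        Named("final") = List::create(Named("h") = h));
  } else if (type == "gru") {
    GruParams p(params);
    const uword G = p.buz.n_elem;
    vec h(G, fill::zeros);
    if (state0.isNotNull()) h = as<vec>(List(state0)["h"]);
    vec h0 = h;
    mat H(G, T), Z(G, T), R(G, T), N(G, T), A(G, T);
    GruStepCache c;
    for (uword t = 0; t < T; ++t) {
      h = gru_step(p, U.col(t), h, c);
      H.col(t) = h; Z.col(t) = c.z; R.col(t) = c.r; N.col(t) = c.n;
      A.col(t) = c.A;
    }
    return List::create(Named("states") = H, Named("h0") = h0,
                        Named("Z") = Z, Named("R") = R, Named("N") = N,
                        Named("A") = A,
                        Named("final") = List::create(Named("h") = h));
  } else if (type == "lstm") {
    LstmParams p(params);
    const uword G = p.bi.n_elem;
    vec h(G, fill::zeros), cst(G, fill::zeros);
    if (state0.isNotNull()) {
      List s0(state0);
      h = as<vec>(s0["h"]); cst = as<vec>(s0["c"]);
    }
    vec h0 = h, c0 = cst;
    mat H(G, T), I(G, T), Fm(G, T), Gm(G, T), O(G, T), Cm(G, T);
    LstmStepCache s;
    for (uword t = 0; t < T; ++t) {
      h = lstm_step(p, U.col(t), h, cst, s);
      cst = s.c;
      H.col(t) = h; I.col(t) = s.i; Fm.col(t) = s.f; Gm.col(t) = s.g;
      O.col(t) = s.o; Cm.col(t) = s.c;
    }
    return List::create(Named("states") = H, Named("h0") = h0,
                        Named("c0") = c0, Named("I") = I, Named("F") = Fm,
                        Named("G") = Gm, Named("O") = O, Named("C") = Cm,
                        Named("final") = List::create(Named("h") = h,
                                                      Named("c") = cst));
  } else if (type == "ssm") {
    SsmParams p(params);
    const uword G = p.a_log.n_elem;
    vec s(G, fill::zeros);
    if (state0.isNotNull()) s = as<vec>(List(state0)["s"]);
    vec s0v = s;
    mat S(G, T), Y(G, T);
    vec s_out;
    for (uword t = 0; t < T; ++t) {
      Y.col(t) = ssm_step(p, U.col(t), s, s_out);
      s = s_out; S.col(t) = s;
    }
    return List::create(Named("states") = Y, Named("S") = S,
                        Named("s0") = s0v,
                        Named("final") = List::create(Named("s") = s));
  }
  stop("unknown core type '%s'", type);
}

// Backward pass. K = 0 requests full BPTT (one reverse sweep). K >= 1
// requests truncated BPTT with warmup semantics: the forward states are the
// full-history states (from core_forward_cpp) and the gradient of the loss
// term at bin t is propagated through at most K steps of history.
// [[Rcpp::export]]
List core_backward_cpp(std::string type, List params, List cache,
                       const arma::mat& U, const arma::mat& d_states,
                       int K = 0) {
  const uword T = U.n_cols;
  mat d_U(U.n_rows, T, fill::zeros);

  if (type == "elman") {
    ElmanParams p(params);
    ElmanGrads g(p);
    mat H = as<mat>(cache["states"]);
    vec h0 = as<vec>(cache["h0"]);
    auto hprev = [&](uword t) -> vec { return t == 0 ? h0 : vec(H.col(t - 1)); };
    if (K <= 0) {
      vec d_h(H.n_rows, fill::zeros);
      for (uword tt = T; tt-- > 0;) {
        d_h += d_states.col(tt);
        vec du(U.n_rows, fill::zeros);
        d_h = elman_step_bwd(p, g, U.col(tt), hprev(tt), H.col(tt), d_h, du);
        d_U.col(tt) += du;
      }
    } else {
      for (uword t = 0; t < T; ++t) {
        if (!any(d_states.col(t) != 0.0)) continue;
        vec d_h = d_states.col(t);
        uword lo = (t + 1 >= (uword)K) ? t + 1 - (uword)K : 0;
        for (uword tt = t + 1; tt-- > lo;) {
          vec du(U.n_rows, fill::zeros);
          d_h = elman_step_bwd(p, g, U.col(tt), hprev(tt), H.col(tt), d_h, du);
          d_U.col(tt) += du;
        }
      }
    }
    return List::create(Named("d_params") = g.toList(), Named("d_U") = d_U);
  } else if (type == "gru") {
    GruParams p(params);
    GruGrads g(p);
    mat H = as<mat>(cache["states"]);
    vec h0 = as<vec>(cache["h0"]);
    mat Z = as<mat>(cache["Z"]), R = as<mat>(cache["R"]),
        N = as<mat>(cache["N"]), A = as<mat>(cache["A"]);
    auto hprev = [&](uword t) -> vec { return t == 0 ? h0 : vec(H.col(t - 1)); };
    auto cac = [&](uword t) {
      GruStepCache c;
      c.z = Z.col(t); c.r = R.col(t); c.n = N.col(t); c.A = A.col(t);
      return c;
    };
    if (K <= 0) {
      vec d_h(H.n_rows, fill::zeros);
      for (uword tt = T; tt-- > 0;) {
        d_h += d_states.col(tt);
        vec du(U.n_rows, fill::zeros);
        GruStepCache c = cac(tt);
        d_h = gru_step_bwd(p, g, U.col(tt), hprev(tt), c, d_h, du);
        d_U.col(tt) += du;
      }
    } else {
      for (uword t = 0; t < T; ++t) {
        if (!any(d_states.col(t) != 0.0)) continue;
        vec d_h = d_states.col(t);
        uword lo = (t + 1 >= (uword)K) ? t + 1 - (uword)K : 0;
        for (uword tt = t + 1; tt-- > lo;) {
          vec du(U.n_rows, fill::zeros);
          GruStepCache c = cac(tt);
          d_h = gru_step_bwd(p, g, U.col(tt), hprev(tt), c, d_h, du);
          d_U.col(tt) += du;
        }
      }
    }
    return List::create(Named("d_params") = g.toList(), Named("d_U") = d_U);
  } else if (type == "lstm") {
    LstmParams p(params);
    LstmGrads g(p);
    mat H = as<mat>(cache["states"]);
    vec h0 = as<vec>(cache["h0"]), c0 = as<vec>(cache["c0"]);
    mat I = as<mat>(cache["I"]), Fm = as<mat>(cache["F"]),
        Gm = as<mat>(cache["G"]), O = as<mat>(cache["O"]),
        Cm = as<mat>(cache["C"]);
    auto hprev = [&](uword t) -> vec { return t == 0 ? h0 : vec(H.col(t - 1)); };
    auto cprev = [&](uword t) -> vec { return t == 0 ? c0 : vec(Cm.col(t - 1)); };
    auto cac = [&](uword t) {
      LstmStepCache s;
      s.i = I.col(t); s.f = Fm.col(t); s.g = Gm.col(t); s.o = O.col(t);
      s.c = Cm.col(t);
      return s;
    };
    if (K <= 0) {
      vec d_h(H.n_rows, fill::zeros), d_c(H.n_rows, fill::zeros);
      for (uword tt = T; tt-- > 0;) {
        d_h += d_states.col(tt);
        vec du(U.n_rows, fill::zeros);
        LstmStepCache s = cac(tt);
        d_h = lstm_step_bwd(p, g, U.col(tt), hprev(tt), cprev(tt), s, d_h,
                            d_c, du);
        d_U.col(tt) += du;
      }
    } else {
      for (uword t = 0; t < T; ++t) {
        if (!any(d_states.col(t) != 0.0)) continue;
        vec d_h = d_states.col(t), d_c(H.n_rows, fill::zeros);
        uword lo = (t + 1 >= (uword)K) ? t + 1 - (uword)K : 0;
        for (uword tt = t + 1; tt-- > lo;) {
          vec du(U.n_rows, fill::zeros);
          LstmStepCache s = cac(tt);
          d_h = lstm_step_bwd(p, g, U.col(tt), hprev(tt), cprev(tt), s, d_h,
                              d_c, du);
          d_U.col(tt) += du;
        }
      }
    }
    return List::create(Named("d_params") = g.toList(), Named("d_U") = d_U);
  } else if (type == "ssm") {
    SsmParams p(params);
    SsmGrads g(p);
    mat S = as<mat>(cache["S"]);
    vec s0 = as<vec>(cache["s0"]);
    auto sprev = [&](uword t) -> vec { return t == 0 ? s0 : vec(S.col(t - 1)); };
    // Output map y_t = C s_t + D u_t (independent of truncation).
    mat d_S(S.n_rows, T, fill::zeros);
    for (uword t = 0; t < T; ++t) {
      vec dy = d_states.col(t);
      if (!any(dy != 0.0)) continue;
      d_S.col(t) += p.C.t() * dy;
      g.C += dy * S.col(t).t();
      g.D += dy * U.col(t).t();
      d_U.col(t) += p.D.t() * dy;
    }
    if (K <= 0) {
      vec d_s(S.n_rows, fill::zeros);
      for (uword tt = T; tt-- > 0;) {
        d_s += d_S.col(tt);
        vec du(U.n_rows, fill::zeros);
        d_s = ssm_rec_bwd(p, g, U.col(tt), sprev(tt), d_s, du);
        d_U.col(tt) += du;
      }
    } else {
      for (uword t = 0; t < T; ++t) {
        if (!any(d_S.col(t) != 0.0)) continue;
        vec d_s = d_S.col(t);
        uword lo = (t + 1 >= (uword)K) ? t + 1 - (uword)K : 0;
        for (uword tt = t + 1; tt-- > lo;) {
          vec du(U.n_rows, fill::zeros);
          d_s = ssm_rec_bwd(p, g, U.col(tt), sprev(tt), d_s, du);
          d_U.col(tt) += du;
        }
      }
    }
    g.finalize(p);
    return List::create(Named("d_params") = g.toList(), Named("d_U") = d_U);
  }
  stop("unknown core type '%s'", type);
}

// TBPTT without warmup: the output at bin t is produced by running the core
// for min(K, t) steps from the null state over bins (t-K+1)..t. Returns the
// resulting output states; the (heavier) gradients are obtained by calling
// core_nowarmup_backward_cpp with the same arguments plus d_states.
// [[Rcpp::export]]
List core_nowarmup_forward_cpp(std::string type, List params,
                               const arma::mat& U, int K) {
  if (K < 1) stop("K must be >= 1");
  const uword T = U.n_cols;
  uword G;
  if (type == "elman") G = as<vec>(params["b"]).n_elem;
  else if (type == "gru") G = as<vec>(params["buz"]).n_elem;
  else if (type == "lstm") G = as<vec>(params["bi"]).n_elem;
  else if (type == "ssm") G = as<vec>(params["a_log"]).n_elem;
  else stop("unknown core type '%s'", type);

  mat OUT(G, T);
  if (type == "elman") {
    ElmanParams p(params);
    for (uword t = 0; t < T; ++t) {
      uword lo = (t + 1 >= (uword)K) ? t + 1 - (uword)K : 0;
      vec h(G, fill::zeros);
      for (uword j = lo; j <= t; ++j) h = elman_step(p, U.col(j), h);
      OUT.col(t) = h;
    }
  } else if (type == "gru") {
    GruParams p(params);
    GruStepCache c;
    for (uword t = 0; t < T; ++t) {
      uword lo = (t + 1 >= (uword)K) ? t + 1 - (uword)K : 0;
      vec h(G, fill::zeros);
      for (uword j = lo; j <= t; ++j) h = gru_step(p, U.col(j), h, c);
      OUT.col(t) = h;
    }
  } else if (type == "lstm") {
    LstmParams p(params);
    LstmStepCache s;
    for (uword t = 0; t < T; ++t) {
      uword lo = (t + 1 >= (uword)K) ? t + 1 - (uword)K : 0;
      vec h(G, fill::zeros), cst(G, fill::zeros);
      for (uword j = lo; j <= t; ++j) { h = lstm_step(p, U.col(j), h, cst, s); cst = s.c; }
      OUT.col(t) = h;
    }
  } else {  // ssm
    SsmParams p(params);
    for (uword t = 0; t < T; ++t) {
      uword lo = (t + 1 >= (uword)K) ? t + 1 - (uword)K : 0;
      vec s(G, fill::zeros), s_out; vec y;
      for (uword j = lo; j <= t; ++j) { y = ssm_step(p, U.col(j), s, s_out); s = s_out; }
      OUT.col(t) = y;
    }
  }
  return List::create(Named("states") = OUT);
}

// Gradients for TBPTT without warmup. Re-runs each K-step window forward
// (storing the per-step cache locally) and backpropagates the loss gradient
// arriving at the window's final output state.
// [[Rcpp::export]]
List core_nowarmup_backward_cpp(std::string type, List params,
                                const arma::mat& U, const arma::mat& d_states,
                                int K) {
  if (K < 1) stop("K must be >= 1");
  const uword T = U.n_cols;
  mat d_U(U.n_rows, T, fill::zeros);

  if (type == "elman") {
    ElmanParams p(params);
    ElmanGrads g(p);
    const uword G = p.b.n_elem;
    for (uword t = 0; t < T; ++t) {
      if (!any(d_states.col(t) != 0.0)) continue;
      uword lo = (t + 1 >= (uword)K) ? t + 1 - (uword)K : 0;
      uword L = t - lo + 1;
      mat H(G, L);
      vec h(G, fill::zeros);
      for (uword j = 0; j < L; ++j) { h = elman_step(p, U.col(lo + j), h); H.col(j) = h; }
      vec d_h = d_states.col(t);
      for (uword j = L; j-- > 0;) {
        vec hp = (j == 0) ? vec(G, fill::zeros) : vec(H.col(j - 1));
        vec du(U.n_rows, fill::zeros);
        d_h = elman_step_bwd(p, g, U.col(lo + j), hp, H.col(j), d_h, du);
        d_U.col(lo + j) += du;
      }
    }
    return List::create(Named("d_params") = g.toList(), Named("d_U") = d_U);
  } else if (type == "gru") {
    GruParams p(params);
    GruGrads g(p);
    const uword G = p.buz.n_elem;
    for (uword t = 0; t < T; ++t) {
      if (!any(d_states.col(t) != 0.0)) continue;
      uword lo = (t + 1 >= (uword)K) ? t + 1 - (uword)K : 0;
      uword L = t - lo + 1;
      mat H(G, L);
      std::vector<GruStepCache> cs(L);
      vec h(G, fill::zeros);
      for (uword j = 0; j < L; ++j) { h = gru_step(p, U.col(lo + j), h, cs[j]); H.col(j) = h; }
      vec d_h = d_states.col(t);
      for (uword j = L; j-- > 0;) {
        vec hp = (j == 0) ? vec(G, fill::zeros) : vec(H.col(j - 1));
        vec du(U.n_rows, fill::zeros);
        d_h = gru_step_bwd(p, g, U.col(lo + j), hp, cs[j], d_h, du);
        d_U.col(lo + j) += du;
      }
    }
    return List::create(Named("d_params") = g.toList(), Named("d_U") = d_U);
  } else if (type == "lstm") {
    LstmParams p(params);
    LstmGrads g(p);
    const uword G = p.bi.n_elem;
    for (uword t = 0; t < T; ++t) {
      if (!any(d_states.col(t) != 0.0)) continue;
      uword lo = (t + 1 >= (uword)K) ? t + 1 - (uword)K : 0;
      uword L = t - lo + 1;
      mat H(G, L), Cm(G, L);
      std::vector<LstmStepCache> cs(L);
      vec h(G, fill::zeros), cst(G, fill::zeros);
      for (uword j = 0; j < L; ++j) {
        h = lstm_step(p, U.col(lo + j), h, cst, cs[j]);
        cst = cs[j].c; H.col(j) = h; Cm.col(j) = cst;
      }
      vec d_h = d_states.col(t), d_c(G, fill::zeros);
      for (uword j = L; j-- > 0;) {
        vec hp = (j == 0) ? vec(G, fill::zeros) : vec(H.col(j - 1));
        vec cp = (j == 0) ? vec(G, fill::zeros) : vec(Cm.col(j - 1));
        vec du(U.n_rows, fill::zeros);
        d_h = lstm_step_bwd(p, g, U.col(lo + j), hp, cp, cs[j], d_h, d_c, du);
        d_U.col(lo + j) += du;
      }
    }
    return List::create(Named("d_params") = g.toList(), Named("d_U") = d_U);
  } else if (type == "ssm") {
    SsmParams p(params);
    SsmGrads g(p);
    const uword G = p.a_log.n_elem;
    for (uword t = 0; t < T; ++t) {
      vec dy = d_states.col(t);
      if (!any(dy != 0.0)) continue;
      uword lo = (t + 1 >= (uword)K) ? t + 1 - (uword)K : 0;
      uword L = t - lo + 1;
      mat S(G, L);
      vec s(G, fill::zeros), s_out;
      for (uword j = 0; j < L; ++j) { ssm_step(p, U.col(lo + j), s, s_out); s = s_out; S.col(j) = s; }
      // output map at window end
      g.C += dy * S.col(L - 1).t();
      g.D += dy * U.col(t).t();
      d_U.col(t) += p.D.t() * dy;
      vec d_s = p.C.t() * dy;
      for (uword j = L; j-- > 0;) {
        vec sp = (j == 0) ? vec(G, fill::zeros) : vec(S.col(j - 1));
        vec du(U.n_rows, fill::zeros);
        d_s = ssm_rec_bwd(p, g, U.col(lo + j), sp, d_s, du);
        d_U.col(lo + j) += du;
      }
    }
    g.finalize(p);
    return List::create(Named("d_params") = g.toList(), Named("d_U") = d_U);
  }
  stop("unknown core type '%s'", type);
}
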