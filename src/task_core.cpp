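#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// LZ76 exhaustive-history parser.
//
// Complexity = number of components of the exhaustive production history that
// terminate in an innovation symbol.  A terminal component that is fully
// reproducible from its prefix (overlap-copy allowed) does not increment the
// count.  Under this convention the periodic window-10 extension of a
// circular history parses to 3 while the direction-breaking extension parses
// to 4, so the deterministic reward rule discriminates them.
// ---------------------------------------------------------------------------
static int lz76_core(const std::vector<int> &s) {
  const int n = (int)s.size();
  int c = 0, i = 0;
  while (i < n) {
    int maxl = 0;
    for (int j = 0; j < i; ++j) {
      int l = 0;
      while (i + l < n && s[j + l] == s[i + l]) ++l;
      if (l > maxl) maxl = l;
    }
    if (i + maxl < n) {   // component ends with an innovation symbol
      ++c;
      i += maxl + 1;
    } else {              // reproducible tail: no innovation, not counted
      i = n;
    }
  }
  return c;
}

// [[Rcpp::export]]
int lz76_int_cpp(IntegerVector x) {
  std::vector<int> s(x.begin(), x.end());
  return lz76_core(s);
}

// Columns of m are independent sequences (integer symbol codes).
// [[Rcpp::export]]
IntegerVector lz76_cols_cpp(IntegerMatrix m) {
  const int nc = m.ncol(), nr = m.nrow();
  IntegerVector out(nc);
  std::vector<int> s(nr);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) s[i] = m(i, j);
    out[j] = lz76_core(s);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Deterministic complexity rule, precomputed over all 3^9 9-symbol histories.
// Index: sum_j h[j] * 3^j with h[0] the OLDEST of the 9 past locations.
// Entry reward_table[idx*3 + a] is 1 if appending location a to that history
// yields the (weakly) highest LZ count among the two legal options, 0 if not,
// -1 for the illegal stay action.
// ---------------------------------------------------------------------------
static std::vector<signed char> g_reward_table;
static const int POW3[10] = {1, 3, 9, 27, 81, 243, 729, 2187, 6561, 19683};

static void build_reward_table() {
  if (!g_reward_table.empty()) return;
  g_reward_table.assign(19683 * 3, -1);
  std::vector<int> h(9);
  for (int idx = 0; idx < 19683; ++idx) {
    int x = idx;
    for (int j = 0; j < 9; ++j) { h[j] = x % 3; x /= 3; }
    const int last = h[8];
    const int o1 = (last + 1) % 3, o2 = (last + 2) % 3;
    std::vector<int> s1(h), s2(h);
    s1.push_back(o1);
    s2.push_back(o2);
    const int c1 = lz76_core(s1), c2 = lz76_core(s2);
    g_reward_table[idx * 3 + o1] = (signed char)(c1 >= c2 ? 1 : 0);
    g_reward_table[idx * 3 + o2] = (signed char)(c2 >= c1 ? 1 : 0);
  }
}

// Rolling task history within one behavioral session.
struct TaskHistory {
  std::vector<int> sess;
  long idx = 0;            // base-3 index of the last <=9 locations, oldest at 3^0
  void reset() { sess.clear(); idx = 0; }
  int len() const { return (int)sess.size(); }
  int last() const { return sess.back(); }
  void push(int a) {
    const int l = (int)sess.size();
    if (l < 9) idx += (long)a * POW3[l];
    else idx = idx / 3 + (long)a * POW3[8];
    sess.push_back(a);
  }
  // Reward of taking action a (a != last) under the complexity rule,
  // BEFORE pushing a.  Short histories compared on the available window.
  int complexity_reward(int a) const {
    const int l = (int)sess.size();
    if (l >= 9) return g_reward_table[idx * 3 + a];
    const int last_ = sess.back();
    const int b = 3 - last_ - a;   // the other legal option
    std::vector<int> sa(sess), sb(sess);
    sa.push_back(a);
    sb.push_back(b);
    return lz76_core(sa) >= lz76_core(sb) ? 1 : 0;
  }
};

// condition codes: 0 = training, 1 = complexity, 2 = p75
// warmup codes: 0 = reward_all, 1 = skip (score the shorter window)
static int env_reward(TaskHistory &th, int a, int condition, double p_reward,
                      int warmup_mode) {
  if (condition == 0) return 1;
  if (condition == 2) return (unif_rand() < p_reward) ? 1 : 0;
  if (th.len() < 9 && warmup_mode == 0) return 1;
  return th.complexity_reward(a);
}

// ---------------------------------------------------------------------------
// Memory-augmented Rescorla-Wagner / softmax agent.
//
// State key: base-(3*ambiguity+1) encoding of the codes of the current and m
// previous locations (most recent in the lowest digit); slots before the
// session start use a fixed sentinel code.  With ambiguity n > 1 each
// location's code is redrawn uniformly among its n codes at every encoding
// event.
// ---------------------------------------------------------------------------
struct QStore {
  std::unordered_map<long long, std::array<double, 3> > q;
  double q_init;
  explicit QStore(double qi) : q_init(qi) {}
  std::array<double, 3> &at(long long key) {
    auto it = q.find(key);
    if (it != q.end()) return it->second;
    std::array<double, 3> v = {{q_init, q_init, q_init}};
    return q.emplace(key, v).first->second;
  }
};

static long long state_key(const std::vector<int> &sess, int memory,
                           int ambiguity) {
  const int base = 3 * ambiguity + 1;
  const int sentinel = 3 * ambiguity;
  const int t = (int)sess.size();   // sess holds locations up to current
  long long key = 0, mult = 1;
  for (int j = 0; j <= memory; ++j) {
    int code;
    const int pos = t - 1 - j;
    if (pos < 0) {
      code = sentinel;
    } else {
      const int loc = sess[pos];
      code = (ambiguity == 1)
                 ? loc
                 : loc * ambiguity + (int)std::floor(unif_rand() * ambiguity);
    }
    key += mult * code;
    mult *= base;
  }
  return key;
}

// [[Rcpp::export]]
List agent_simulate_cpp(double alpha, NumericVector tau, NumericVector kappa,
                        int memory, int ambiguity, IntegerVector condition,
                        IntegerVector n_trials, double p_reward,
                        int warmup_mode, double q_init) {
  build_reward_table();
  const int n_sessions = n_trials.size();
  int total = 0;
  for (int s = 0; s < n_sessions; ++s) total += n_trials[s];
  IntegerVector choices(total), rewards(total), session(total);
  QStore Q(q_init);
  TaskHistory th;
  int k = 0;
  for (int s = 0; s < n_sessions; ++s) {
    const double tau_s = tau[s % tau.size()];
    const double kappa_s = kappa[s % kappa.size()];
    th.reset();
    for (int t = 0; t < n_trials[s]; ++t) {
      int a, r;
      if (t == 0) {
        a = (int)std::floor(unif_rand() * 3.0);
        if (a > 2) a = 2;
        r = (condition[s] == 2) ? ((unif_rand() < p_reward) ? 1 : 0) : 1;
        th.push(a);
      } else {
        const int cur = th.last();
        const int a1 = (cur + 1) % 3, a2 = (cur + 2) % 3;
        const long long key = state_key(th.sess, memory, ambiguity);
        std::array<double, 3> &qv = Q.at(key);
        const double q1 = qv[a1], q2 = qv[a2];
        const double mx = q1 > q2 ? q1 : q2;
        const double e1 = std::exp((q1 - mx) / tau_s);
        const double e2 = std::exp((q2 - mx) / tau_s);
        a = (unif_rand() < e1 / (e1 + e2)) ? a1 : a2;
        r = env_reward(th, a, condition[s], p_reward, warmup_mode);
        const bool uturn = (t >= 2) && (a == th.sess[t - 2]);
        const double u = uturn ? (1.0 - kappa_s) * (double)r : (double)r;
        qv[a] += alpha * (u - qv[a]);
        th.push(a);
      }
      choices[k] = a;
      rewards[k] = r;
      session[k] = s + 1;
      ++k;
    }
  }
  return List::create(_["choices"] = choices, _["rewards"] = rewards,
                      _["session"] = session);
}

// kind codes: 0 = random, 1 = repetitive, 2 = greedy_oracle, 3 = wsls
// [[Rcpp::export]]
List baseline_simulate_cpp(int kind, int condition, IntegerVector n_trials,
                           double p_reward, int warmup_mode) {
  build_reward_table();
  const int n_sessions = n_trials.size();
  int total = 0;
  for (int s = 0; s < n_sessions; ++s) total += n_trials[s];
  IntegerVector choices(total), rewards(total), session(total);
  TaskHistory th;
  int k = 0;
  for (int s = 0; s < n_sessions; ++s) {
    th.reset();
    int dir = (unif_rand() < 0.5) ? 1 : 2;  // wsls direction (+1 or +2 mod 3)
    int last_r = 1;
    for (int t = 0; t < n_trials[s]; ++t) {
      int a, r;
      if (t == 0) {
        a = (kind == 1) ? 0 : (int)std::floor(unif_rand() * 3.0);
        if (a > 2) a = 2;
        r = (condition == 2) ? ((unif_rand() < p_reward) ? 1 : 0) : 1;
      } else {
        const int cur = th.last();
        const int a1 = (cur + 1) % 3, a2 = (cur + 2) % 3;
        switch (kind) {
          case 0:
            a = (unif_rand() < 0.5) ? a1 : a2;
            break;
          case 1:
            a = a1;  // fixed circular direction
            break;
          case 2: {  // greedy on the complexity rule, uniform on ties
            const int r1 = th.complexity_reward(a1);
            const int r2 = th.complexity_reward(a2);
            if (r1 == r2) a = (unif_rand() < 0.5) ? a1 : a2;
            else a = (r1 > r2) ? a1 : a2;
            break;
          }
          default: {  // win-stay-lose-switch on movement direction
            if (!last_r) dir = 3 - dir;
            a = (cur + dir) % 3;
            break;
          }
        }
        r = env_reward(th, a, condition, p_reward, warmup_mode);
      }
      th.push(a);
      last_r = r;
      choices[k] = a;
      rewards[k] = r;
      session[k] = s + 1;
      ++k;
    }
  }
  return List::create(_["choices"] = choices, _["rewards"] = rewards,
                      _["session"] = session);
}

// Re-score an arbitrary no-repeat sequence under the complexity rule.
// Returns per-trial rewards; trial 1 scored per warm-up convention.
// [[Rcpp::export]]
IntegerVector rescore_cpp(IntegerVector seq, int warmup_mode) {
  build_reward_table();
  const int n = seq.size();
  IntegerVector rewards(n);
  TaskHistory th;
  for (int t = 0; t < n; ++t) {
    if (t == 0) {
      rewards[t] = 1;
    } else {
      rewards[t] = (th.len() < 9 && warmup_mode == 0)
                       ? 1
                       : th.complexity_reward(seq[t]);
    }
    th.push(seq[t]);
  }
  return rewards;
}

// Constrained surrogates: first symbol uniform over 3, each next uniform over
// the 2 legal symbols.  Columns are independent sequences.
// [[Rcpp::export]]
IntegerMatrix surrogates_cpp(int len, int count) {
  IntegerMatrix out(len, count);
  for (int j = 0; j < count; ++j) {
    int cur = (int)std::floor(unif_rand() * 3.0);
    if (cur > 2) cur = 2;
    out(0, j) = cur;
    for (int i = 1; i < len; ++i) {
      const int nxt =
          (unif_rand() < 0.5) ? (cur + 1) % 3 : (cur + 2) % 3;
      out(i, j) = nxt;
      cur = nxt;
    }
  }
  return out;
}
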