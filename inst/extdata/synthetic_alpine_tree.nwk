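(((((((s006:0.6456163112,s012:0.6456163112):0.08624965959,s010:0.7318659707):0.4582166801,(((s019:0.02574796751,s025:0.02574796751):0.3195847573,s020:0.3453327248):0.007922274355,s003:0.3532549992):0.8368276517):0.2788630288,((s009:0.6291423111,s013:0.6291423111):0.2435074244,s005:0.8726497355):0.5962959442):0.5226876811,((s004:0.5557913369,s016:0.5557913369):0.0302990153,s014:0.5860903522):1.405543009):0.03133154191,((((s002:0.3249303052,s021:0.3249303052):0.3350879861,s011:0.6600182913):0.2922582494,s008:0.9522765407):0.05047396528,((s007:0.2710050428,s023:0.2710050428):0.01528302571,s022:0.2862880685):0.7164624375):1.020214397):1.259003407,((((s018:0.09526999909,s024:0.09526999909):0.3091229198,s015:0.4043929189):0.06001018387,s017:0.4644031027):0.1008391602,s001:0.5652422629):2.716726047);
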