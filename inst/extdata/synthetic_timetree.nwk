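((((((t2:185.921118689,(t6:143.852015618,(t17:101.892974799,(t50:40.9754252519,t49:40.9754252519):60.9175495468):41.9590408196):42.0691030709):28.0399926226,((t21:83.1546583575,t20:83.1546583575):4.28329666498,((t71:25.8406273942,t70:25.8406273942):0.363304101439,(t78:20.1878183356,(t90:15.3326362158,t89:15.3326362158):4.85518211976):6.01611316007):61.2340235268):126.523156289):30.7786172279,((t12:128.774739276,((t48:43.050893325,t47:43.050893325):58.2607282702,((((t42:57.4835721645,(t43:56.7114422419,((t116:1.0947524625,t115:1.0947524625):32.5800614846,t61:33.6748139471):23.0366282948):0.772129922538):13.3003604801,(t45:47.3880084597,t44:47.3880084597):23.3959241849):4.979826928,t24:75.7637595726):15.573219938,((t38:60.8742658771,t37:60.8742658771):15.8655185562,t23:76.7397844333):14.5971950773):9.97464208462):27.4631176812):88.9353587111,t1:217.710097987):27.0296305522):55.7758340339,((((((t86:17.6913721625,t85:17.6913721625):46.0453159007,t34:63.7366880631):54.6727602521,t15:118.409448315):17.0156475148,t7:135.42509583):41.6590627624,t3:177.084158592):83.6157527479,(t96:10.3901215118,t95:10.3901215118):250.309789829):39.8156512333):11.6812766663,((t16:116.439620014,(t82:18.7375865572,t81:18.7375865572):97.7020334565):89.2529492529,((t4:168.392563202,(((t102:5.99377909719,t101:5.99377909719):51.8948865134,t41:57.8886656106):1.42752039429,t40:59.3161860048):109.076377198):23.4250792227,((t56:36.4195936624,(t88:17.6455390497,t87:17.6455390497):18.7740546127):107.460337747,((t58:34.9930782667,t57:34.9930782667):5.74424260409,(t108:3.79111855273,t107:3.79111855273):36.946202318):103.142610539):47.9377110154):13.8749268414):106.504269973):37.80316076,(((t60:34.7593339395,t59:34.7593339395):160.989353528,(t80:19.1463683679,t79:19.1463683679):176.602319099):122.965006042,(((t94:13.6180024272,t93:13.6180024272):230.530457935,(t98:8.76966166114,t97:8.76966166114):235.378798701):31.9530985074,((((((t36:62.3088085007,t35:62.3088085007):73.4010151795,(t13:125.188131397,(((t67:28.7116413308,(t106:4.86732618725,t105:4.86732618725):23.8443151436):70.1261008591,(t46:46.5830220017,(t104:5.75433192748,t103:5.75433192748):40.8286900742):52.2547201883):5.42598266765,(t25:75.472474297,((t74:24.1104950769,t73:24.1104950769):49.9914550776,(((t112:3.25369973505,t111:3.25369973505):57.2606943858,t39:60.5143941209):7.66934077037,t30:68.1837348912):5.91821526326):1.37052414249):28.7912505606):20.9244065398):10.5216922828):34.8030098404,((t11:129.142593461,t10:129.142593461):39.9390319778,(((t120:0.35101661363,t119:0.35101661363):55.152003,((t55:37.0236050194,t54:37.0236050194):14.7004758339,((t118:0.975945678003,t117:0.975945678003):21.9261452777,t75:22.9020909557):28.8219898976):3.77893876033):18.2165188605,t28:73.7195384742):95.3620869649):1.43120808147):55.3302176158,(((((t66:31.6275827685,(t114:1.9549080429,t113:1.9549080429):29.6726747256):9.1787520178,t51:40.8063347863):43.9574475764,(t27:74.4188781274,t26:74.4188781274):10.3449042353):14.0444307689,t18:98.8082131316):61.3476351506,(((t72:24.6158014362,(t110:3.29619064316,t109:3.29619064316):21.3196107931):8.10536592113,(t77:21.9310175773,t76:21.9310175773):10.7901497801):91.4255534849,t14:124.146720842):36.00912744):65.6872028542):18.7939553809,(((t53:39.0427751985,t52:39.0427751985):56.9184560174,t19:95.9612312159):119.63423639,(t33:64.5640341731,t32:64.5640341731):151.031433433):29.0415389112):8.23355600789,((((t9:129.33859282,t8:129.33859282):21.9567677763,(((t69:27.8969374959,t68:27.8969374959):18.7612832155,(t100:7.03966744722,t99:7.03966744722):39.6185532642):33.8133057627,((t63:33.303040099,t62:33.303040099):34.6240657727,t31:67.9271058717):12.5444206024):70.8238341218):0.594436140201,t5:151.889796736):80.7956985075,(((t29:69.6321730578,(t65:32.4888737148,t64:32.4888737148):37.143299343):8.83636459886,t22:78.4685376567):133.424384654,((t92:14.799595216,t91:14.799595216):92.2643863432,(t84:17.7050722178,t83:17.7050722178):89.3589093414):104.828940752):20.7925729326):20.1850672816):23.2309963445):42.6121346394):31.2863064909);
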